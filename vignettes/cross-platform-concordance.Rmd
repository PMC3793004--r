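---
title: "Cross-platform concordance analysis of miRNA profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform concordance analysis of miRNA profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirconcord)
```

## The problem

Profiling the same RNA on different miRNA technologies gives systematically
different answers. Sequencing platforms measure composition at great depth
but with library-preparation bias; RT-qPCR panels measure a pre-designed
target set on an inverted log2 scale with a hard detection cutoff;
hybridization counters measure without amplification, so their signal sits
directly on top of optical/chemical background. None of them observes the
molecular truth. `mirconcord` implements a comparison framework for this
situation: it harmonizes what the platforms can be compared on, normalizes
them a single way, and quantifies agreement in detection and in fold
change, using cross-platform consensus as the stand-in for truth.

This vignette documents the model assumptions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Harmonized reference and panels

All statistics are computed on canonical mature-miRNA targets. Source
annotations are collapsed (`merge_reference()`) when they share an
identical mature sequence — the same molecule transcribed from different
genomic loci — or when a platform chemistry cannot distinguish them
(explicit merge groups, e.g. close paralog families). Merging is a
union-find over both rules, so overlapping groups union transitively; the
canonical ID is the lexicographically smallest member, which makes merging
deterministic, idempotent, and reversible through the recorded member
lists. Assay IDs absent from the reference (obsolete annotations) go to an
explicit discard bucket — every input ID is accounted for exactly once.

When two assays map to one canonical target, their measurements are
combined by a unit-dependent rule: counts are summed (preserving total
signal), Cq values take the per-sample minimum (the strongest signal,
preserving detection status). The *concordant panel* — the intersection of
all platform panels — is the only set on which consensus truth is defined;
per-pair statistics use each pair's mutual targets.

## Normalization model

One strategy is applied to every platform: **linear total-count scaling**.
Each sample is multiplied so all samples of a platform reach the arithmetic
mean of the sample totals. This preserves each platform's magnitude while
equalizing depth, and leaves within-sample ratios untouched. Mixing
normalization strategies across platforms would itself create
discordance, so uniformity is the point.

Per-technology pre-processing happens first:

* **RT-qPCR.** Cq is linearized as `2^(cutoff − Cq)` with the detection
  cutoff (default 36 cycles) as the zero baseline; Cq at or beyond the
  cutoff, or missing, maps to 0. The inverse (`linear_to_cq()`) reports 0
  as the cutoff sentinel. We deliberately use `2^(cutoff − cq)` rather than
  `2^(cutoff − cq) − 1`: the simplest reading of "cutoff as zero baseline",
  with censoring handled by the detection flag rather than by deforming the
  scale. After scaling, the log2 column reports the back-converted Cq.
* **Hybridization.** Background is subtracted per sample as the negative-
  control mean plus two standard deviations (sample sd, n−1 denominator —
  appropriate at n = 8 probes), flooring at zero; whether to floor or allow
  negatives was open, and flooring was chosen so that "at or below
  threshold" and "undetected" coincide. Then a technical factor from the six
  positive spikes (mean spike sum over this sample's spike sum) rescales all
  values, matching vendor convention for global technical factors. Order:
  background first, then spikes, then total-count scaling — the spike factor
  is multiplicative so the detection boundary (corrected value > 0) is
  unaffected by the order.
* **NGS.** Counts go straight to total-count scaling; detection, however,
  is called on *raw* annotated reads (default threshold: 1 read), because
  scaling makes count thresholds meaningless.

**Replicates.** The combination rule is: a target is detected in a cell
line when the platform's rule passes in a strict majority of replicates
(2k > n; for duplicates that means both), and the reported linear value is
the mean of replicate linear values with failing replicates contributing 0.
Undetected targets report linear 0. This is robust to single-replicate
dropout and matches triplicate/duplicate designs. Percentile ranks are
computed among detected targets within each (platform, cell line), average
rank for ties, scaled into (0, 1].

## Detection truth and concordance statistics

With no spike-in ground truth, consensus across chemistries is the best
available evidence: a data point (miRNA × cell line) on the concordant
panel is a **true positive** when ≥ 3 of 4 platforms detect it
(`min_platforms` configurable), else a **true negative**. Sensitivity and
specificity follow directly and are undefined (an error, or `NA` in the
pipeline report) when the truth has no positives or no negatives.

**Pair buckets.** Every point detected by at least one member of a pair is
classified by (both vs one member) × (0/1/2 outside platforms also
detecting), giving the six-bucket breakdown, the single/both totals, and
percent-detected-by-both.

**Weighted pair score.** The score uses two postulates: detection of a
highly expressed miRNA carries more evidence, and corroboration by
independent platforms reduces the chance a detection is spurious. Each
pair-visible point m contributes sign s_m = ±1 (both / one member) with
weight

w_m = p_m · (1 + k_m)/3,

p_m the mean percentile rank over the platforms detecting m (only
detecting platforms carry expression evidence; if a single platform
detects, p_m is that platform's rank), k_m the number of non-pair
platforms detecting. The score is Σs·w / Σw. The published account of this
statistic fixes its ingredients, monotonicity, and the ±1 endpoints but
not the formula; this linear choice is the simplest construction
satisfying all of them, so interior score values are this package's own
convention — the endpoints (identical sets → exactly 1, disjoint sets →
exactly −1, any weights) are the portable guarantees, and the test suite
asserts them as such.

**Overlap views.** `venn_counts()` tabulates detection subsets per data
point (default) or pooled per miRNA over cell lines; `quintile_dispersion()`
bins single-platform-only or all-platform detections by expression
percentile, the view that shows single-platform detections concentrating at
low abundance.

## Fold-change accuracy

Fold changes `log2(x/y)` are computed per platform over all cell-line
pairs, restricted to targets detected in both lines — undetected values are
excluded, not floored, to avoid pseudo-count artifacts. Capture bias fixed
across samples cancels here, which is why cross-platform fold-change
agreement can be high even when absolute profiles disagree. Total-count
scaling adds one shared constant per (platform, line pair) — a composition
shift — which Pearson correlation ignores and which is identical across
platforms when panels and biases match.

Platform pairs are compared by Pearson R with Fisher-z 95% CI and two-sided
p (via `stats::cor.test`; the tests re-derive the CI independently),
percent sign agreement (a fold change of exactly 0 agrees with anything — a
tie is not a contradiction), agreement by expression quintile (binning on
the mean of the two platforms' base percentiles), and agreement by
fold-change magnitude with default bin edges 0.585/1/1.585 log2 units —
roughly 1.5-fold, 2-fold, 3-fold, expressing the "close to one" / "two
fold" / "three fold or more" anchors; edges are configurable. The binning
variable is the mean |log2 FC| across participating platforms (maximum
available via `summarise = "max"`). AP mode keeps records shared by all
platforms and requires every platform to match the direction of the mean.
Reported precision follows the conventions of the field's tables:
percentages to integers, scores to 2 dp, sensitivity to 3 dp (unrounded
values are always retained alongside).

## The synthetic-data generator

`generate_truth()` draws, under one seed: per-miRNA log2 baselines
(Normal(6, 3) by default), a differentially expressed subset (30% of
expressed miRNAs; per non-reference line, effects uniform in ±[0.585, 4]
log2), and per-(miRNA, platform) capture biases (Normal(0, 1) log2) fixed
across cell lines — the library-preparation distortion whose cancellation
in fold changes the analysis relies on. Only a fraction of a large
reference is expressed at all in one cell lineage (`expressed_fraction`,
default 0.5); unexpressed targets get zero abundance everywhere, which is
what gives the consensus truth its true-negative side and keeps observed
panel fractions in the realistic 30–60% range. True fold changes are
effect differences, independent of bias.

Platform emulators:

* `simulate_ngs()`: Poisson counts around depth × within-panel relative
  abundance (sequencing measures composition); `noise = FALSE` returns the
  expectations for deterministic checks. Default depths 3·10^6 (duplicate)
  and 7·10^6 (single replicate) annotated reads — the order of magnitude of
  annotated-read yields per sample in small-RNA studies.
* `simulate_qpcr()`: Cq = c0 − abundance_log2 + Normal(0, 0.25) cycles,
  censored to missing at 36; one cycle per doubling by construction.
* `simulate_hyb()`: counts = gain × abundance × per-sample lognormal
  efficiency + Normal(bg_mean, bg_sd) floored at 0, with 8 negative probes
  (background only) and 6 positive spikes (levels × efficiency). The
  additive background with no amplification is the mechanism that
  selectively destroys its low-abundance sensitivity — raising `bg_mean`
  monotonically depresses its sensitivity and every score it participates
  in, which the tests assert as a trend.

The default scenario mirrors the comparison's scale: 4 cell lines, a
1719-target reference, panels 1719/1719/722/631 sharing a 517-target core
(scaled-down scenarios shrink the partial panels proportionally, never
below the core). `zero_noise_scenario()` switches off bias, noise,
censoring and panel differences; on it the pipeline must return sensitivity
1.0 everywhere, weighted scores exactly 1, R = 1 and 100% agreement in
every bin — the parameter-recovery contract the acceptance tests enforce.

**What the generator does not emulate:** read-level sequences and adapter
chemistry, isomiR heteroplasmy, biological replicate variation (all
replication is technical), cross-hybridization between paralogs,
inter-plate qPCR calibration drift, and overdispersion beyond Poisson
(negative-binomial mixing is the natural extension but technical replicates
of the same library are close to Poisson). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not that any real platform will achieve these numbers.

## Numerical choices and degenerate inputs

* Totals after scaling agree to 1e−9 relative tolerance (asserted).
* Cq linearization round-trips to floating-point ulp; the algebraic
  identity is exact.
* A sample with zero total signal, a zero spike sum, fewer than 2 negative
  probes, a pair of identical platforms, truths without positives (for
  sensitivity) or negatives (for specificity), and fewer than 3 shared
  records (for correlation) are errors naming the offender; empty
  concordant intersections warn; empty agreement bins report `NA`, never 0.
* Percentile ties: average rank. Bucket boundaries: a value equal to the
  background threshold becomes 0 and is undetected; Cq exactly at the
  cutoff is undetected; quintile bins are [0,.2), …, [.8,1].
* All randomness lives in the generator, one seed per call, recorded in the
  outputs; the analysis modules are deterministic, and identical
  configuration + seed reproduces reports byte-for-byte.

## Problem sizes used in the test suite

Unit and property tests run on cubes of ≤ 50 miRNAs against brute-force
enumeration oracles; end-to-end recovery uses 40–80 targets; the
expression-dependent-noise contrast uses 600 targets with deep NGS
(10^7 reads) under a fixed seed; trend assertions average 20 seeded
replicates. These sizes were chosen as the smallest at which the asserted
contrasts are unambiguous.

## Known limitations

* The weighted score's interior values are convention-dependent (see
  above); compare them only within this package.
* Consensus truth is biased toward the majority chemistry: three platforms
  sharing a blind spot will mislabel a real miRNA as a true negative.
* Fold-change records require detection in both lines, so strong
  on/off regulation is invisible to the accuracy statistics.
* Total-count scaling leaves a composition shift in per-pair fold changes;
  it is shared across platforms only insofar as panels overlap.
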