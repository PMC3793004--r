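# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Generate ground-truth miRNA abundances for a multi-platform study
#'
#' Draws the latent quantities every simulated platform measures: per-miRNA
#' baseline abundances on the log2 scale, differential-expression effects per
#' (miRNA, cell line) for a chosen fraction of miRNAs, and per-(miRNA,
#' platform) capture biases that are *fixed across cell lines* — the
#' library-preparation/chemistry distortion that shifts absolute levels but
#' cancels out of within-platform fold changes. The first cell line is the
#' reference (all effects 0); DE miRNAs receive, in each other line, a
#' uniform effect of random sign within `effect_range_log2`. The true log2
#' fold change between lines X and Y for miRNA m is
#' `de_spec[m, X] - de_spec[m, Y]`, independent of platform bias.
#'
#' Only a fraction of a large reference is expressed at all in any one cell
#' lineage; the remaining targets get zero abundance (`-Inf` log2 baseline)
#' in every line, so they sit below every platform's detection limit and
#' populate the true-negative side of the consensus truth. Differential
#' expression is drawn among expressed miRNAs only.
#'
#' @param n_mirna number of miRNAs in the reference.
#' @param expressed_fraction fraction of the reference expressed in the
#'   lineage (default 0.5); unexpressed targets have zero abundance in all
#'   lines.
#' @param lines cell-line names (>= 2).
#' @param platforms platform names receiving capture biases.
#' @param de_fraction fraction of miRNAs that are differentially expressed.
#' @param effect_range_log2 length-2 positive interval for |effect| (log2).
#' @param bias_sd_log2 sd of the per-(miRNA, platform) capture bias (log2).
#' @param baseline_mean_log2,baseline_sd_log2 normal parameters of the
#'   baseline log2 abundance.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return Object of class `synthetic_truth`: list with `ids`, `lines`,
#'   `platforms`, `baseline_log2` (named vector), `de_ids`, `de_spec`
#'   (matrix miRNA x line), `bias_log2` (matrix miRNA x platform), `seed`.
#' @export
generate_truth <- function(n_mirna = 1719,
                           lines = c("lineA", "lineB", "lineC", "lineD"),
                           platforms = c("solid", "illumina", "mircury",
                                         "ncounter"),
                           de_fraction = 0.3,
                           expressed_fraction = 0.5,
                           effect_range_log2 = c(0.585, 4),
                           bias_sd_log2 = 1,
                           baseline_mean_log2 = 6,
                           baseline_sd_log2 = 3,
                           seed = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (expressed_fraction < 0 || expressed_fraction > 1)
    stop("expressed_fraction must be in [0, 1]")
  if (length(effect_range_log2) != 2 || any(effect_range_log2 < 0) ||
      diff(effect_range_log2) < 0)
    stop("effect_range_log2 must be a non-negative increasing interval")
  stopifnot(bias_sd_log2 >= 0, length(lines) >= 2)
  ids <- sprintf("mir%04d", seq_len(n_mirna))
  with_seed(seed, {
    baseline <- stats::setNames(
      stats::rnorm(n_mirna, baseline_mean_log2, baseline_sd_log2), ids)
    expressed <- sort(sample(ids, round(expressed_fraction * n_mirna)))
    baseline[setdiff(ids, expressed)] <- -Inf
    n_de <- round(de_fraction * length(expressed))
    de_ids <- sort(sample(expressed, n_de))
    de_spec <- matrix(0, n_mirna, length(lines), dimnames = list(ids, lines))
    if (n_de > 0 && length(lines) > 1) {
      for (cl in lines[-1]) {
        eff <- stats::runif(n_de, effect_range_log2[1], effect_range_log2[2]) *
          sample(c(-1, 1), n_de, replace = TRUE)
        de_spec[de_ids, cl] <- eff
      }
    }
    bias <- matrix(stats::rnorm(n_mirna * length(platforms), 0, bias_sd_log2),
                   n_mirna, length(platforms), dimnames = list(ids, platforms))
    structure(list(ids = ids, lines = lines, platforms = platforms,
                   baseline_log2 = baseline, expressed_ids = expressed,
                   de_ids = de_ids, de_spec = de_spec, bias_log2 = bias,
                   seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$ids), "miRNAs x", length(x$lines),
      "cell lines,", length(x$expressed_ids), "expressed,",
      length(x$de_ids), "differentially expressed, platforms:",
      paste(x$platforms, collapse = ", "), "\n")
  invisible(x)
}

# Latent linear abundance of each panel target in one cell line, including
# the platform's capture bias.
latent_abundance <- function(truth, platform, line, panel) {
  2^(truth$baseline_log2[panel] + truth$de_spec[panel, line] +
       truth$bias_log2[panel, platform])
}

#' Assign per-platform target panels with a controlled shared core
#'
#' Builds platform panels of the requested sizes such that the intersection
#' over all platforms is exactly a common core of `n_core` targets:
#' platforms smaller than the full reference receive the core plus extra
#' targets drawn disjointly from the remainder.
#'
#' @param ids reference target IDs.
#' @param sizes named integer vector of panel sizes (>= `n_core` each).
#' @param n_core size of the all-platform core.
#' @param seed integer seed.
#' @return named list of sorted ID vectors, one per platform.
#' @export
generate_panels <- function(ids, sizes, n_core, seed = 1) {
  stopifnot(all(sizes >= n_core), all(sizes <= length(ids)), n_core >= 0)
  need <- sum(pmax(sizes[sizes < length(ids)] - n_core, 0))
  if (need > length(ids) - n_core)
    stop("panel sizes incompatible with a disjoint-extras core of ", n_core)
  with_seed(seed, {
    core <- sample(ids, n_core)
    pool <- sample(setdiff(ids, core))
    used <- 0
    panels <- lapply(names(sizes), function(pl) {
      s <- sizes[[pl]]
      if (s == length(ids)) return(sort(ids))
      take <- pool[seq_len(s - n_core) + used]
      used <<- used + (s - n_core)
      sort(c(core, take))
    })
    names(panels) <- names(sizes)
    panels
  })
}

#' Simulate an NGS read-count table
#'
#' Per replicate sample, annotated read counts are Poisson with mean
#' `depth * relative_abundance`, where the relative abundance of each panel
#' target includes the platform's capture bias and is normalized within the
#' panel (sequencing measures composition). The expected sample total is
#' `depth`. With `noise = FALSE` the expected counts themselves are returned
#' (a deterministic table for exact parameter-recovery checks).
#'
#' @param truth a [generate_truth()] result.
#' @param platform platform name in `truth`.
#' @param depth expected annotated reads per sample.
#' @param n_replicates technical replicates per cell line.
#' @param seed integer seed.
#' @param panel target IDs assayed (default: full reference).
#' @param noise draw Poisson counts (default) or return expectations.
#' @return A `read_count` [measurement_table()].
#' @export
simulate_ngs <- function(truth, platform, depth = 1e6, n_replicates = 2,
                         seed = 1, panel = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) stop("depth must be positive")
  if (is.null(panel)) panel <- truth$ids
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         cell_line = truth$lines,
                         stringsAsFactors = FALSE)
  nm <- paste(samples$cell_line, samples$replicate, sep = ".")
  with_seed(seed, {
    vals <- sapply(seq_len(nrow(samples)), function(i) {
      ab <- latent_abundance(truth, platform, samples$cell_line[i], panel)
      lambda <- depth * ab / sum(ab)
      if (noise) stats::rpois(length(lambda), lambda) else lambda
    })
    dimnames(vals) <- list(panel, nm)
    measurement_table(platform, "read_count", vals)
  })
}

#' Simulate an RT-qPCR Cq table
#'
#' Cq values fall one cycle per doubling of abundance:
#' `Cq = c0 - abundance_log2 + Normal(0, noise_sd)` with the platform's
#' capture bias inside `abundance_log2`. Values at or beyond `cutoff` are
#' censored to `NA` (no amplification called), matching the background rule
#' applied downstream.
#'
#' @param truth a [generate_truth()] result.
#' @param platform platform name in `truth`.
#' @param c0 cycle intercept: the Cq of a target with log2 abundance 0.
#' @param noise_sd technical noise sd on the Cq scale (cycles).
#' @param cutoff censoring cutoff (default 36).
#' @param n_replicates technical replicates per cell line.
#' @param seed integer seed.
#' @param panel target IDs assayed.
#' @return A `cq` [measurement_table()].
#' @export
simulate_qpcr <- function(truth, platform, c0 = 40, noise_sd = 0.25,
                          cutoff = 36, n_replicates = 3, seed = 1,
                          panel = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(panel)) panel <- truth$ids
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         cell_line = truth$lines,
                         stringsAsFactors = FALSE)
  nm <- paste(samples$cell_line, samples$replicate, sep = ".")
  with_seed(seed, {
    vals <- sapply(seq_len(nrow(samples)), function(i) {
      ab_log2 <- log2(latent_abundance(truth, platform,
                                       samples$cell_line[i], panel))
      cq <- c0 - ab_log2 + stats::rnorm(length(panel), 0, noise_sd)
      ifelse(cq >= cutoff, NA_real_, cq)
    })
    dimnames(vals) <- list(panel, nm)
    measurement_table(platform, "cq", vals)
  })
}

#' Simulate a hybridization probe-count table with control probes
#'
#' Target counts are `gain * abundance * efficiency + background`, where
#' abundance is the latent linear level (capture bias included), efficiency
#' is a per-sample lognormal factor emulating hybridization/purification
#' variation, and background is `bg_mean + Normal(0, bg_sd)` floored at 0.
#' There is no amplification step, so low-abundance targets sink into the
#' additive background — the mechanism that depresses this technology's
#' sensitivity. Each sample carries 8 negative probes (background only) and
#' 6 positive spikes (`spike_levels * efficiency`), which
#' [subtract_background()] and [spike_normalize()] consume.
#'
#' @param truth a [generate_truth()] result.
#' @param platform platform name in `truth`.
#' @param gain counts per linear abundance unit.
#' @param bg_mean,bg_sd background mean and sd (counts); must be >= 0.
#' @param spike_levels 6 positive spike input levels (counts).
#' @param efficiency_sd_log2 sd of the per-sample log2 efficiency factor.
#' @param n_replicates technical replicates per cell line.
#' @param seed integer seed.
#' @param panel target IDs assayed.
#' @return A `probe_count` [measurement_table()] with control matrices.
#' @export
simulate_hyb <- function(truth, platform, gain = 0.15, bg_mean = 12,
                         bg_sd = 6, spike_levels = c(8000, 2000, 500, 125,
                                                     31, 8),
                         efficiency_sd_log2 = 0.2, n_replicates = 3,
                         seed = 1, panel = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (bg_mean < 0 || bg_sd < 0) stop("background parameters must be >= 0")
  if (length(spike_levels) != 6) stop("exactly 6 spike levels are required")
  if (gain < 0) stop("gain must be >= 0")
  if (is.null(panel)) panel <- truth$ids
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         cell_line = truth$lines,
                         stringsAsFactors = FALSE)
  nm <- paste(samples$cell_line, samples$replicate, sep = ".")
  with_seed(seed, {
    eff <- 2^stats::rnorm(nrow(samples), 0, efficiency_sd_log2)
    vals <- sapply(seq_len(nrow(samples)), function(i) {
      ab <- latent_abundance(truth, platform, samples$cell_line[i], panel)
      pmax(gain * ab * eff[i] + bg_mean +
             stats::rnorm(length(ab), 0, bg_sd), 0)
    })
    dimnames(vals) <- list(panel, nm)
    neg <- pmax(matrix(bg_mean + stats::rnorm(8 * nrow(samples), 0, bg_sd),
                       8, nrow(samples)), 0)
    pos <- outer(spike_levels, eff)
    colnames(neg) <- colnames(pos) <- nm
    measurement_table(platform, "probe_count", vals,
                      positive_spikes = pos, negative_probes = neg)
  })
}

#' Default four-platform simulation scenario
#'
#' The study design the generator emulates: four cell lines measured on two
#' NGS-like platforms (one duplicate, one single-replicate), a qPCR-like
#' platform in triplicate with Cq censoring at 36, and a hybridization-like
#' platform in triplicate with control probes. The reference holds 1719
#' targets; platform panels of 1719/1719/722/631 targets share a 517-target
#' all-platform core. When the scenario is scaled down (smaller `n_mirna`),
#' the partial panels shrink proportionally but never below `n_core`.
#'
#' @param n_mirna,n_core reference and core panel sizes.
#' @param de_fraction fraction of expressed miRNAs that are differentially
#'   expressed.
#' @param expressed_fraction fraction of the reference expressed at all.
#' @param bias_sd_log2 per-(miRNA, platform) capture-bias sd (log2).
#' @param noise simulate measurement noise (set `FALSE` for deterministic
#'   expected-value tables).
#' @return A scenario list consumed by [simulate_scenario()].
#' @export
default_scenario <- function(n_mirna = 1719, n_core = 517,
                             de_fraction = 0.3, expressed_fraction = 0.5,
                             bias_sd_log2 = 1, noise = TRUE) {
  list(
    n_mirna = n_mirna,
    lines = c("lineA", "lineB", "lineC", "lineD"),
    de_fraction = de_fraction,
    expressed_fraction = expressed_fraction,
    effect_range_log2 = c(0.585, 4),
    bias_sd_log2 = bias_sd_log2,
    baseline_mean_log2 = 6,
    baseline_sd_log2 = 3,
    panel_sizes = c(solid = n_mirna, illumina = n_mirna,
                    mircury = max(n_core, round(n_mirna * 722 / 1719)),
                    ncounter = max(n_core, round(n_mirna * 631 / 1719))),
    n_core = n_core,
    noise = noise,
    platforms = list(
      solid = list(kind = "ngs", depth = 3e6, n_replicates = 2),
      illumina = list(kind = "ngs", depth = 7e6, n_replicates = 1),
      mircury = list(kind = "qpcr", c0 = 40, noise_sd = 0.25, cutoff = 36,
                     n_replicates = 3),
      ncounter = list(kind = "hyb", gain = 0.15, bg_mean = 12, bg_sd = 6,
                      spike_levels = c(8000, 2000, 500, 125, 31, 8),
                      efficiency_sd_log2 = 0.2, n_replicates = 3)))
}

#' Noise-free validation scenario
#'
#' A deterministic small-scale scenario for parameter-recovery checks: all
#' four platforms assay the same full panel, capture biases and measurement
#' noise are switched off, baselines sit far from every detection limit so
#' nothing is censored, and NGS tables contain expected counts rather than
#' Poisson draws. On such data every platform must detect everything, every
#' pairwise weighted score must be exactly 1, and cross-platform fold-change
#' correlations must be exactly 1 — any deviation is a pipeline defect, not
#' noise.
#'
#' @param n_mirna number of targets.
#' @param de_fraction fraction of differentially expressed miRNAs.
#' @return A scenario list for [simulate_scenario()].
#' @export
zero_noise_scenario <- function(n_mirna = 80, de_fraction = 0.3) {
  sc <- default_scenario(n_mirna = n_mirna, n_core = n_mirna,
                         de_fraction = de_fraction,
                         expressed_fraction = 0.85, bias_sd_log2 = 0,
                         noise = FALSE)
  sc$baseline_mean_log2 <- 10
  sc$baseline_sd_log2 <- 1.5
  sc$panel_sizes <- c(solid = n_mirna, illumina = n_mirna,
                      mircury = n_mirna, ncounter = n_mirna)
  sc$platforms$solid$depth <- 1e5
  sc$platforms$illumina$depth <- 2e5
  sc$platforms$mircury$c0 <- 34
  sc$platforms$ncounter$gain <- 0.5
  sc$platforms$ncounter$bg_mean <- 0
  sc
}

#' Simulate a complete multi-platform study from a scenario
#'
#' Draws the ground truth, assigns platform panels, and simulates one
#' measurement table per platform. All randomness derives from `seed`;
#' identical seed and scenario give bit-identical output.
#'
#' @param scenario a scenario list (see [default_scenario()]).
#' @param seed integer seed.
#' @return list with `truth` ([generate_truth()]), `panel` (a
#'   [reference_panel()] carrying the platform panels) and `tables` (named
#'   list of [measurement_table()]s).
#' @export
simulate_scenario <- function(scenario = default_scenario(), seed = 1) {
  platforms <- names(scenario$platforms)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                    length(platforms) + 2))
  truth <- generate_truth(
    n_mirna = scenario$n_mirna, lines = scenario$lines,
    platforms = platforms, de_fraction = scenario$de_fraction,
    expressed_fraction = if (is.null(scenario$expressed_fraction)) 1 else
      scenario$expressed_fraction,
    effect_range_log2 = scenario$effect_range_log2,
    bias_sd_log2 = scenario$bias_sd_log2,
    baseline_mean_log2 = scenario$baseline_mean_log2,
    baseline_sd_log2 = scenario$baseline_sd_log2,
    seed = sub[1])
  panels <- generate_panels(truth$ids, scenario$panel_sizes,
                            scenario$n_core, seed = sub[2])
  targets <- data.frame(canonical_id = truth$ids,
                        members = I(as.list(truth$ids)),
                        sequence = NA_character_,
                        stringsAsFactors = FALSE)
  panel <- reference_panel(targets, panels)
  noise <- !isFALSE(scenario$noise)
  tables <- lapply(seq_along(platforms), function(i) {
    pl <- platforms[i]
    cfg <- scenario$platforms[[pl]]
    pnl <- panels[[pl]]
    switch(cfg$kind,
      ngs = simulate_ngs(truth, pl, depth = cfg$depth,
                         n_replicates = cfg$n_replicates,
                         seed = sub[i + 2], panel = pnl, noise = noise),
      qpcr = simulate_qpcr(truth, pl, c0 = cfg$c0,
                           noise_sd = if (noise) cfg$noise_sd else 0,
                           cutoff = cfg$cutoff,
                           n_replicates = cfg$n_replicates,
                           seed = sub[i + 2], panel = pnl),
      hyb = simulate_hyb(truth, pl, gain = cfg$gain, bg_mean = cfg$bg_mean,
                         bg_sd = if (noise) cfg$bg_sd else 0,
                         spike_levels = cfg$spike_levels,
                         efficiency_sd_log2 =
                           if (noise) cfg$efficiency_sd_log2 else 0,
                         n_replicates = cfg$n_replicates,
                         seed = sub[i + 2], panel = pnl),
      stop("unknown platform kind: ", cfg$kind))
  })
  names(tables) <- platforms
  list(truth = truth, panel = panel, tables = tables, seed = seed)
}
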