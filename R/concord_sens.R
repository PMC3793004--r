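# [id, line] matrix slice of one platform, robust to singleton dimensions
cube_slice <- function(cube, platform) {
  matrix(cube[, , platform], dim(cube)[1], dim(cube)[2],
         dimnames = dimnames(cube)[1:2])
}

#' Pairwise detection breakdown for a platform pair
#'
#' Classifies every data point detected by at least one member of the pair
#' into six buckets by (a) whether both members or only one detect it and
#' (b) how many of the non-pair platforms also detect it (0, 1 or 2):
#' `minus`/`minus2`/`minus3` for single-member detections with 0/1/2 outside
#' corroborations, `plus`/`plus2`/`plus3` for both-member detections.
#'
#' @param cube logical detection cube `[id, line, platform]` without missing
#'   calls (e.g. `truth$detection` from [define_truth()]).
#' @param pair character vector of two distinct platform names.
#' @return list of class `pair_score` with `pair`, `counts` (named integer
#'   vector of the six buckets), `n_single`, `n_both`.
#' @export
pair_counts <- function(cube, pair) {
  stopifnot(is.array(cube), length(dim(cube)) == 3, length(pair) == 2)
  if (pair[1] == pair[2]) stop("pair members must be distinct platforms")
  platforms <- dimnames(cube)[[3]]
  unknown <- setdiff(pair, platforms)
  if (length(unknown)) stop("unknown platform(s): ",
                            paste(unknown, collapse = ", "))
  others <- setdiff(platforms, pair)
  a <- cube_slice(cube, pair[1])
  b <- cube_slice(cube, pair[2])
  k <- Reduce(`+`, lapply(others, function(p) cube_slice(cube, p) * 1L),
              matrix(0L, nrow(a), ncol(a)))
  either <- a | b
  both <- a & b
  counts <- integer(6)
  names(counts) <- c("minus", "minus2", "minus3", "plus", "plus2", "plus3")
  for (kk in 0:2) {
    counts[kk + 1] <- sum(either & !both & k == kk)
    counts[kk + 4] <- sum(both & k == kk)
  }
  structure(list(pair = pair, counts = counts,
                 n_single = sum(counts[1:3]), n_both = sum(counts[4:6])),
            class = "pair_score")
}

#' Percentage of pair-visible points detected by both members
#'
#' @param counts a `pair_score` from [pair_counts()].
#' @return list with `percent` (unrounded), `percent_rounded` (nearest
#'   integer, the reporting precision) — both `NA` when no point is detected
#'   by either member.
#' @export
percent_both <- function(counts) {
  stopifnot(inherits(counts, "pair_score"))
  denom <- counts$n_both + counts$n_single
  if (denom == 0) return(list(percent = NA_real_, percent_rounded = NA_real_))
  pct <- 100 * counts$n_both / denom
  list(percent = pct, percent_rounded = round(pct))
}

#' Weighted pairwise concordance score
#'
#' A detection-concordance statistic in \[-1, 1\] for a platform pair.
#' Every data point m detected by at least one pair member contributes
#' sign `s_m = +1` (both members detect) or `-1` (one member only), with
#' weight `w_m = p_m * (1 + k_m) / 3`, where `p_m` is the mean expression
#' percentile rank over the platforms detecting m (expression evidence) and
#' `k_m` in 0..2 counts the non-pair platforms detecting m (independent
#' corroboration). The score is `sum(s*w) / sum(w)`: exactly 1 when the two
#' members detect identical point sets, exactly -1 when no point is detected
#' by both, regardless of the weights.
#'
#' @param cube logical detection cube without missing calls.
#' @param percentiles numeric cube of percentile ranks aligned with `cube`
#'   (from [percentile_cube()]), `NA` where not detected.
#' @param pair character vector of two distinct platform names.
#' @return list with `score` (`NA` when no point is detected by either
#'   member), `score_rounded` (2 dp, the reporting precision), `n_points`.
#' @export
weighted_pair_score <- function(cube, percentiles, pair) {
  stopifnot(identical(dim(cube), dim(percentiles)))
  pc <- pair_counts(cube, pair)   # validates pair; reuses bucket logic
  platforms <- dimnames(cube)[[3]]
  others <- setdiff(platforms, pair)
  a <- cube_slice(cube, pair[1])
  b <- cube_slice(cube, pair[2])
  either <- which(a | b)
  if (!length(either))
    return(list(score = NA_real_, score_rounded = NA_real_, n_points = 0L))
  ndet <- Reduce(`+`, lapply(platforms, function(p) cube_slice(cube, p) * 1L))
  psum <- Reduce(`+`, lapply(platforms, function(p) {
    x <- cube_slice(percentiles, p)
    x[!cube_slice(cube, p)] <- 0
    x[is.na(x)] <- 0
    x
  }))
  p_m <- psum[either] / ndet[either]
  k <- Reduce(`+`, lapply(others, function(p) cube_slice(cube, p) * 1L),
              matrix(0L, nrow(a), ncol(a)))
  s <- ifelse((a & b)[either], 1, -1)
  w <- p_m * (1 + k[either]) / 3
  score <- sum(s * w) / sum(w)
  list(score = score, score_rounded = round(score, 2),
       n_points = length(either))
}

#' Detection-overlap (Venn) counts across platforms
#'
#' Tabulates, for every non-empty platform subset, how many units are
#' detected by exactly that subset. The unit is a (miRNA, cell line) data
#' point by default, or — with `unit = "pooled"` — a miRNA, counted as
#' detected by a platform when detected in at least one cell line.
#'
#' @param cube logical detection cube without missing calls.
#' @param unit `"data_point"` or `"pooled"`.
#' @return named integer vector; names are `+`-joined platform subsets in
#'   cube order. Subsets partition all detected units.
#' @export
venn_counts <- function(cube, unit = c("data_point", "pooled")) {
  unit <- match.arg(unit)
  platforms <- dimnames(cube)[[3]]
  if (length(platforms) < 2) stop("venn counts need >= 2 platforms")
  det <- if (unit == "pooled") {
    sapply(platforms, function(p) apply(cube[, , p, drop = FALSE], 1, any))
  } else {
    sapply(platforms, function(p) as.vector(cube_slice(cube, p)))
  }
  det <- matrix(det, ncol = length(platforms))
  key <- apply(det, 1, function(row) paste(platforms[row], collapse = "+"))
  tab <- table(key[key != ""])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Expression-quintile dispersion of detection subsets
#'
#' Reproduces the percentile breakdown of single-platform versus
#' all-platform detections: points detected by exactly one platform
#' (`subset_rule = "single_platform"`) are typically low-expressed, while
#' points detected by every platform concentrate in the upper quintiles.
#' For each platform, qualifying points are binned by that platform's own
#' percentile rank into quintiles \[0,.2), \[.2,.4), \[.4,.6), \[.6,.8),
#' \[.8,1\].
#'
#' @param cube logical detection cube without missing calls.
#' @param percentiles aligned percentile cube (see [percentile_cube()]).
#' @param subset_rule `"single_platform"` (detected by that platform only) or
#'   `"all_platforms"` (detected by every platform).
#' @return numeric matrix platform x 5 of bin fractions (rows sum to 1 when
#'   any point qualifies, otherwise `NA`).
#' @export
quintile_dispersion <- function(cube, percentiles,
                                subset_rule = c("single_platform",
                                                "all_platforms")) {
  subset_rule <- match.arg(subset_rule)
  platforms <- dimnames(cube)[[3]]
  ndet <- Reduce(`+`, lapply(platforms, function(p) cube_slice(cube, p) * 1L))
  out <- matrix(NA_real_, length(platforms), 5,
                dimnames = list(platforms, paste0("q", 1:5)))
  for (p in platforms) {
    qualifies <- if (subset_rule == "single_platform")
      cube_slice(cube, p) & ndet == 1 else ndet == length(platforms)
    pct <- cube_slice(percentiles, p)[qualifies]
    pct <- pct[!is.na(pct)]
    if (!length(pct)) next
    bins <- pmin(floor(pct * 5) + 1, 5)
    out[p, ] <- tabulate(bins, 5) / length(pct)
  }
  out
}

#' Pairwise concordance report over all platform pairs
#'
#' One row per unordered platform pair with the six detection buckets,
#' single/both totals, percent detected by both, and the weighted
#' concordance score.
#'
#' @param cube logical detection cube without missing calls.
#' @param percentiles aligned percentile cube.
#' @return data frame, `choose(n_platforms, 2)` rows.
#' @export
pair_report <- function(cube, percentiles) {
  platforms <- dimnames(cube)[[3]]
  pairs <- utils::combn(platforms, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    pc <- pair_counts(cube, pr)
    pb <- percent_both(pc)
    ws <- weighted_pair_score(cube, percentiles, pr)
    data.frame(platform_a = pr[1], platform_b = pr[2],
               t(pc$counts), n_single = pc$n_single, n_both = pc$n_both,
               percent_both = pb$percent_rounded,
               weighted_score = ws$score_rounded,
               stringsAsFactors = FALSE)
  }))
}
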