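#' Log2 fold changes between two cell lines on one platform
#'
#' Computes `log2(linear_X / linear_Y)` per target for one platform and one
#' oriented cell-line pair, restricted to targets detected in *both* lines
#' on that platform (undetected values are excluded, not floored, so no
#' pseudo-count artifacts enter the comparison). `base_percentile` is the
#' mean of the target's percentile ranks in the two lines and carries the
#' expression level of the comparison.
#'
#' @param profile a `normalized_profile` data frame for one platform.
#' @param line_pair character vector `c(X, Y)`; fold change is X over Y.
#' @return data frame with columns `canonical_id`, `line_pair`, `platform`,
#'   `log2_fc`, `base_percentile`.
#' @export
fold_changes <- function(profile, line_pair) {
  stopifnot(length(line_pair) == 2)
  x <- profile[profile$cell_line == line_pair[1], ]
  y <- profile[profile$cell_line == line_pair[2], ]
  if (!nrow(x) || !nrow(y))
    stop("platform '", profile$platform[1], "' lacks cell line(s): ",
         paste(line_pair[c(!nrow(x), !nrow(y))], collapse = ", "))
  y <- y[match(x$canonical_id, y$canonical_id), ]
  both <- x$detected & y$detected
  if (any(both & (x$linear == 0 | y$linear == 0)))
    stop("zero linear value on a target flagged detected")
  data.frame(canonical_id = x$canonical_id[both],
             line_pair = paste(line_pair, collapse = "/"),
             platform = profile$platform[1],
             log2_fc = log2(x$linear[both] / y$linear[both]),
             base_percentile = (x$percentile[both] + y$percentile[both]) / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold changes for all cell-line pairs of one platform
#'
#' @param profile a `normalized_profile` data frame for one platform.
#' @param lines cell lines to combine; default all profiled lines, giving
#'   `choose(n, 2)` oriented pairs in sorted-name order.
#' @return row-bound [fold_changes()] records.
#' @export
all_fold_changes <- function(profile, lines = NULL) {
  if (is.null(lines)) lines <- sort(unique(profile$cell_line))
  pairs <- utils::combn(lines, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) fold_changes(profile, pr)))
}

merge_records <- function(records_a, records_b) {
  m <- merge(records_a, records_b, by = c("canonical_id", "line_pair"),
             suffixes = c("_a", "_b"))
  m[order(m$line_pair, m$canonical_id), , drop = FALSE]
}

#' Pearson correlation of log2 fold changes between two platforms
#'
#' Correlates the shared (target, line pair) fold-change records of two
#' platforms. The 95% confidence interval uses the Fisher z transform and
#' the p value is the usual two-sided t test, as implemented by
#' [stats::cor.test()].
#'
#' @param records_a,records_b [fold_changes()] records from two platforms.
#' @return list with `r`, `ci95` (length 2, `NA` when n < 4), `p`, `n`.
#' @export
pearson_log2fc <- function(records_a, records_b) {
  m <- merge_records(records_a, records_b)
  if (nrow(m) < 3)
    stop("need >= 3 shared fold-change records, got ", nrow(m))
  ct <- stats::cor.test(m$log2_fc_a, m$log2_fc_b, method = "pearson")
  list(r = unname(ct$estimate),
       ci95 = if (nrow(m) > 3) as.numeric(ct$conf.int) else c(NA_real_, NA_real_),
       p = ct$p.value, n = nrow(m))
}

fc_sign_agrees <- function(a, b) a == 0 | b == 0 | sign(a) == sign(b)

#' Sign agreement of fold changes between two platforms
#'
#' The percentage of shared records whose fold-change direction
#' (up/down-regulated) matches. A log2 fold change of exactly 0 agrees with
#' any direction: a tie is not a contradiction.
#'
#' @param records_a,records_b [fold_changes()] records from two platforms.
#' @return list with `percent`, `n`.
#' @export
sign_agreement <- function(records_a, records_b) {
  m <- merge_records(records_a, records_b)
  if (!nrow(m)) stop("no shared fold-change records")
  list(percent = 100 * mean(fc_sign_agrees(m$log2_fc_a, m$log2_fc_b)),
       n = nrow(m))
}

#' Fold-change sign agreement binned by expression percentile
#'
#' Bins shared records by the mean of the two platforms' `base_percentile`
#' into quintiles and reports the sign-agreement percentage per bin — the
#' view that separates platforms whose accuracy is flat across expression
#' from those that degrade at low abundance.
#'
#' @param records_a,records_b [fold_changes()] records from two platforms.
#' @return data frame with `bin` (1..5), `percent` (`NA` for empty bins),
#'   `n`.
#' @export
agreement_by_percentile <- function(records_a, records_b) {
  m <- merge_records(records_a, records_b)
  pct <- (m$base_percentile_a + m$base_percentile_b) / 2
  bins <- pmin(floor(pct * 5) + 1, 5)
  agree <- fc_sign_agrees(m$log2_fc_a, m$log2_fc_b)
  out <- data.frame(bin = 1:5, percent = NA_real_, n = 0L)
  for (b in 1:5) {
    sel <- bins == b
    out$n[b] <- sum(sel)
    if (any(sel)) out$percent[b] <- 100 * mean(agree[sel])
  }
  out
}

#' Fold-change sign agreement binned by fold-change magnitude
#'
#' Bins records by mean absolute log2 fold change across the participating
#' platforms, with default bin edges at 0.585, 1 and 1.585 log2 units
#' (roughly < 1.5-fold, 1.5-2-fold, 2-3-fold, >= 3-fold). Two modes:
#' \describe{
#'   \item{Paired}{two platforms; agreement = same fold-change direction.}
#'   \item{AP}{all platforms (>= 3); records shared by every platform;
#'     agreement = every platform matches the direction of the mean fold
#'     change.}
#' }
#'
#' @param records_list list of [fold_changes()] record frames, one per
#'   platform (exactly 2 for `"Paired"`, >= 3 for `"AP"`).
#' @param mode `"Paired"` or `"AP"`.
#' @param edges interior bin edges on the |log2 FC| axis.
#' @param summarise how the per-platform |log2 FC| values are combined into
#'   the binning variable: the mean (default) or the maximum.
#' @return data frame with `bin` label, `percent` (`NA` for empty bins), `n`.
#' @export
agreement_by_magnitude <- function(records_list, mode = c("Paired", "AP"),
                                   edges = c(0.585, 1, 1.585),
                                   summarise = c("mean", "max")) {
  mode <- match.arg(mode)
  summarise <- match.arg(summarise)
  if (mode == "Paired" && length(records_list) != 2)
    stop("Paired mode takes exactly 2 platforms")
  if (mode == "AP" && length(records_list) < 3)
    stop("AP mode needs >= 3 platforms")
  keys <- lapply(records_list, function(r) paste(r$canonical_id, r$line_pair))
  shared <- Reduce(intersect, keys)
  fc <- sapply(seq_along(records_list), function(i)
    records_list[[i]]$log2_fc[match(shared, keys[[i]])])
  fc <- matrix(fc, nrow = length(shared))
  mag <- if (summarise == "mean") rowMeans(abs(fc)) else
    apply(abs(fc), 1, max)
  agree <- if (mode == "Paired") {
    fc_sign_agrees(fc[, 1], fc[, 2])
  } else {
    apply(fc, 1, function(v) all(fc_sign_agrees(v, mean(v))))
  }
  breaks <- c(0, edges, Inf)
  bins <- findInterval(mag, breaks, rightmost.closed = TRUE)
  labels <- paste0("[", breaks[-length(breaks)], ",",
                   c(edges, "Inf"), ")")
  out <- data.frame(bin = labels, percent = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
  for (b in seq_along(labels)) {
    sel <- bins == b
    out$n[b] <- sum(sel)
    if (any(sel)) out$percent[b] <- 100 * mean(agree[sel])
  }
  out
}

#' Full accuracy summary for one platform pair
#'
#' @param records_a,records_b [fold_changes()] records from two platforms.
#' @return list of class `agreement_summary` with `pair`, `n`, `pearson`
#'   (list `r`, `ci95`, `p`), `sign_agreement_pct`, `by_percentile`,
#'   `by_magnitude` (Paired mode).
#' @export
agreement_summary <- function(records_a, records_b) {
  pr <- pearson_log2fc(records_a, records_b)
  sa <- sign_agreement(records_a, records_b)
  structure(list(pair = c(records_a$platform[1], records_b$platform[1]),
                 n = pr$n, pearson = pr,
                 sign_agreement_pct = sa$percent,
                 by_percentile = agreement_by_percentile(records_a, records_b),
                 by_magnitude = agreement_by_magnitude(
                   list(records_a, records_b), mode = "Paired")),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("agreement_summary ", x$pair[1], " vs ", x$pair[2], ": n = ", x$n,
      ", R = ", round(x$pearson$r, 3), " [",
      paste(round(x$pearson$ci95, 3), collapse = ", "), "], sign agreement ",
      round(x$sign_agreement_pct), "%\n", sep = "")
  invisible(x)
}
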