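#' Construct a per-platform measurement table
#'
#' Raw measurements for one platform: a target-by-sample matrix plus sample
#' metadata. Unit kinds are `read_count` (annotated small-RNA-seq reads),
#' `cq` (RT-qPCR quantification cycles; lower = more abundant; missing
#' encoded as `NA`, never 0) and `probe_count` (hybridization counts, which
#' must carry 6 positive spike rows and 8 negative control probe rows as
#' separate control matrices).
#'
#' @param platform platform name.
#' @param unit_kind one of `"read_count"`, `"cq"`, `"probe_count"`.
#' @param values numeric matrix target x sample; rownames are target IDs,
#'   colnames are `cellline.replicate` sample labels.
#' @param samples data frame with columns `sample`, `cell_line`, `replicate`
#'   matching `colnames(values)`; derived from the column names if omitted.
#' @param positive_spikes,negative_probes control matrices (probe_count
#'   only), columns matching `values`.
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(platform, unit_kind, values, samples = NULL,
                              positive_spikes = NULL, negative_probes = NULL) {
  unit_kind <- match.arg(unit_kind, c("read_count", "cq", "probe_count"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have target rownames and sample colnames")
  if (is.null(samples)) samples <- parse_sample_names(colnames(values))
  stopifnot(identical(samples$sample, colnames(values)))
  if (unit_kind != "cq" && any(values < 0, na.rm = TRUE))
    stop("count-like values must be non-negative")
  if (unit_kind == "probe_count") {
    if (is.null(positive_spikes) || is.null(negative_probes))
      stop("probe_count tables require positive_spikes and negative_probes")
    stopifnot(ncol(positive_spikes) == ncol(values),
              ncol(negative_probes) == ncol(values))
  }
  structure(list(platform = platform, unit_kind = unit_kind,
                 values = values, samples = samples,
                 positive_spikes = positive_spikes,
                 negative_probes = negative_probes,
                 background_threshold = NULL, spike_factors = NULL),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("measurement_table [", x$platform, ", ", x$unit_kind, "]: ",
      nrow(x$values), " targets x ", ncol(x$values), " samples (",
      length(unique(x$samples$cell_line)), " cell lines)\n", sep = "")
  invisible(x)
}

parse_sample_names <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad))
    stop("sample names must be 'cellline.replicate': ",
         paste(nm[bad], collapse = ", "))
  data.frame(
    sample = nm,
    cell_line = vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
                       character(1)),
    replicate = as.integer(vapply(parts, function(p) p[length(p)], character(1))),
    stringsAsFactors = FALSE)
}

#' Subtract hybridization background from probe counts
#'
#' Per sample, the background threshold is the mean of the negative control
#' probes plus two sample standard deviations (n-1 denominator); every target
#' value is replaced by `max(0, value - threshold)`. A value at or below the
#' threshold therefore becomes 0 and is treated as undetected downstream.
#' Thresholds are recorded in `$background_threshold`.
#'
#' @param table a `probe_count` [measurement_table()].
#' @return The corrected table.
#' @export
subtract_background <- function(table) {
  stopifnot(inherits(table, "measurement_table"),
            table$unit_kind == "probe_count")
  neg <- table$negative_probes
  if (is.null(neg) || nrow(neg) < 2)
    stop("background correction needs >= 2 negative control probes per sample")
  thr <- apply(neg, 2, function(v) mean(v) + 2 * stats::sd(v))
  table$values <- pmax(sweep(table$values, 2, thr), 0)
  table$background_threshold <- thr
  table
}

#' Spike-based technical normalization of probe counts
#'
#' Corrects per-sample hybridization/purification efficiency using the six
#' positive spike controls: the per-sample factor is the arithmetic mean of
#' all samples' spike sums divided by this sample's spike sum, and every
#' target value and negative probe is multiplied by it. Factors are recorded
#' in `$spike_factors`.
#'
#' @param table a `probe_count` [measurement_table()].
#' @return The normalized table.
#' @export
spike_normalize <- function(table) {
  stopifnot(inherits(table, "measurement_table"),
            table$unit_kind == "probe_count")
  pos <- table$positive_spikes
  if (is.null(pos)) stop("positive spike controls are required")
  sums <- colSums(pos)
  if (any(sums == 0))
    stop("spike sum is zero for sample(s): ",
         paste(colnames(pos)[sums == 0], collapse = ", "))
  f <- mean(sums) / sums
  table$values <- sweep(table$values, 2, f, `*`)
  table$negative_probes <- sweep(table$negative_probes, 2, f, `*`)
  table$spike_factors <- f
  table
}

#' Linearize a quantification cycle (Cq) value
#'
#' RT-qPCR reports abundance on an inverted log2 scale: each cycle earlier
#' means roughly a doubling of template. Linearization inverts this with the
#' detection cutoff as the zero baseline: values at or beyond the cutoff
#' (or missing) map to 0, otherwise to `2^(cutoff - cq)`.
#'
#' @param cq numeric vector of Cq values (`NA` = no amplification).
#' @param cutoff detection cutoff cycle, default 36.
#' @return Non-negative linear abundances, same length as `cq`.
#' @examples
#' cq_to_linear(26)        # 1024
#' cq_to_linear(36)        # 0 (at cutoff)
#' @export
cq_to_linear <- function(cq, cutoff = 36) {
  stopifnot(cutoff > 0)
  out <- ifelse(is.na(cq) | cq >= cutoff, 0, 2^(cutoff - cq))
  out
}

#' Back-convert a linear abundance to the Cq scale
#'
#' Inverse of [cq_to_linear()]: positive abundances map to
#' `cutoff - log2(linear)`; a zero abundance (not detected) is reported as
#' the cutoff sentinel.
#'
#' @param linear non-negative numeric vector.
#' @param cutoff detection cutoff cycle, default 36.
#' @return Cq values.
#' @export
linear_to_cq <- function(linear, cutoff = 36) {
  if (any(linear < 0, na.rm = TRUE)) stop("linear abundance must be >= 0")
  ifelse(linear == 0, cutoff, cutoff - log2(linear))
}

#' Linear total-count scaling
#'
#' The single normalization shared by every platform: each sample is
#' multiplied so all samples reach a common total signal. With
#' `target_total = "mean"` (default) the common total is the arithmetic mean
#' of the sample totals, which preserves the platform's overall magnitude
#' while equalizing depth. Within-sample ratios between targets are
#' unchanged.
#'
#' @param values numeric matrix target x sample of linear abundances.
#' @param target_total `"mean"` or a positive number.
#' @return list with `values` (scaled matrix), `factors` (per-sample scale
#'   factors) and `target_total`.
#' @export
total_count_scale <- function(values, target_total = "mean") {
  values <- as.matrix(values)
  totals <- colSums(values)
  if (any(totals == 0))
    stop("total signal is zero for sample(s): ",
         paste(colnames(values)[totals == 0], collapse = ", "))
  tt <- if (identical(target_total, "mean")) mean(totals) else {
    stopifnot(is.numeric(target_total), target_total > 0)
    target_total
  }
  f <- tt / totals
  list(values = sweep(values, 2, f, `*`), factors = f, target_total = tt)
}

majority <- function(x) sum(x) * 2 > length(x)

#' Normalize one platform's measurements into comparable profiles
#'
#' Runs the per-technology pre-processing and the shared total-count scaling,
#' then combines replicates into one profile per cell line:
#' \describe{
#'   \item{probe_count}{background corrected ([subtract_background()]),
#'     spike normalized ([spike_normalize()]), then scaled; detected when the
#'     corrected count is > 0 in a majority of replicates.}
#'   \item{cq}{each replicate linearized with [cq_to_linear()], then scaled;
#'     detected when Cq is below the cutoff in a majority of replicates; the
#'     `log2` column reports the back-converted Cq on the normalized scale.}
#'   \item{read_count}{scaled; detected when the *raw* annotated read count
#'     reaches `min_reads` in a majority of replicates.}
#' }
#' The reported linear value is the mean of replicate linear values (failing
#' replicates contribute 0); undetected targets report linear 0. Percentile
#' ranks are computed among detected targets within each cell line (average
#' rank for ties, scaled into (0, 1]).
#'
#' @param table a [measurement_table()] with canonical target IDs as rows.
#' @param cq_cutoff Cq detection cutoff (default 36).
#' @param min_reads minimum raw reads for NGS detection (default 1).
#' @return A data frame of class `normalized_profile` with columns
#'   `platform`, `canonical_id`, `cell_line`, `linear`, `log2`, `detected`,
#'   `percentile` (NA when not detected).
#' @export
normalize_platform <- function(table, cq_cutoff = 36, min_reads = 1) {
  stopifnot(inherits(table, "measurement_table"))
  raw <- table$values
  if (table$unit_kind == "probe_count") {
    table <- spike_normalize(subtract_background(table))
    lin <- table$values
    det_rep <- lin > 0
  } else if (table$unit_kind == "cq") {
    lin <- apply(raw, 2, cq_to_linear, cutoff = cq_cutoff)
    dimnames(lin) <- dimnames(raw)
    det_rep <- !is.na(raw) & raw < cq_cutoff
  } else {
    lin <- raw
    det_rep <- raw >= min_reads
  }
  scaled <- total_count_scale(lin)$values

  lines <- unique(table$samples$cell_line)
  out <- do.call(rbind, lapply(lines, function(cl) {
    cols <- table$samples$sample[table$samples$cell_line == cl]
    detected <- apply(det_rep[, cols, drop = FALSE], 1, majority)
    linear <- rowMeans(scaled[, cols, drop = FALSE])
    linear[!detected] <- 0
    lg <- if (table$unit_kind == "cq") linear_to_cq(linear, cq_cutoff)
          else ifelse(linear > 0, log2(linear), NA_real_)
    pct <- rep(NA_real_, length(linear))
    if (any(detected))
      pct[detected] <- rank(linear[detected], ties.method = "average") /
        sum(detected)
    data.frame(platform = table$platform, canonical_id = rownames(raw),
               cell_line = cl, linear = linear, log2 = lg,
               detected = detected, percentile = pct,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("normalized_profile", "data.frame")
  out
}

#' Read a measurement TSV into a [measurement_table()]
#'
#' Format: first column the target ID, remaining columns named
#' `cellline.replicate`. For probe-count tables, control rows are carried in
#' the same file with IDs prefixed `POS_` (positive spikes) and `NEG_`
#' (negative probes). Missing Cq values are encoded as `NA`.
#'
#' @param path file path.
#' @param platform platform name.
#' @param unit_kind unit kind of the table.
#' @return A [measurement_table()].
#' @export
read_measurement_tsv <- function(path, platform, unit_kind) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  pos <- m[startsWith(ids, "POS_"), , drop = FALSE]
  neg <- m[startsWith(ids, "NEG_"), , drop = FALSE]
  tgt <- m[!startsWith(ids, "POS_") & !startsWith(ids, "NEG_"), , drop = FALSE]
  measurement_table(platform, unit_kind, tgt,
                    positive_spikes = if (nrow(pos)) pos else NULL,
                    negative_probes = if (nrow(neg)) neg else NULL)
}

#' Write a measurement table to TSV (controls prefixed POS_/NEG_)
#' @param table a [measurement_table()].
#' @param path output file path.
#' @export
write_measurement_tsv <- function(table, path) {
  m <- table$values
  if (!is.null(table$positive_spikes)) {
    pos <- table$positive_spikes
    neg <- table$negative_probes
    rownames(pos) <- paste0("POS_", seq_len(nrow(pos)))
    rownames(neg) <- paste0("NEG_", seq_len(nrow(neg)))
    m <- rbind(m, pos, neg)
  }
  df <- data.frame(canonical_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write normalized profiles to TSV
#' @param profile a `normalized_profile` data frame.
#' @param path output file path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
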