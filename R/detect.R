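#' Assemble the detection cube from normalized profiles
#'
#' Stacks per-platform detection flags into a boolean cube indexed
#' (canonical_id, cell_line, platform). Targets outside a platform's panel
#' are `NA` for that platform — absent assays are never counted against a
#' platform. Every platform must cover every cell line.
#'
#' @param profiles list of `normalized_profile` data frames (one per
#'   platform, from [normalize_platform()]).
#' @param ids optional character vector restricting/ordering the target axis;
#'   default: union of all profiled targets.
#' @return logical 3-d array `[id, cell_line, platform]` with `NA` where a
#'   platform does not assay a target.
#' @export
call_detection <- function(profiles, ids = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  platforms <- vapply(profiles, function(p) p$platform[1], character(1))
  names(profiles) <- platforms
  lines <- sort(unique(unlist(lapply(profiles, function(p) p$cell_line))))
  for (p in profiles) {
    missing <- setdiff(lines, unique(p$cell_line))
    if (length(missing))
      stop("platform '", p$platform[1], "' is missing cell line(s): ",
           paste(missing, collapse = ", "))
  }
  if (is.null(ids))
    ids <- sort(unique(unlist(lapply(profiles, function(p) p$canonical_id))))
  cube <- array(NA, dim = c(length(ids), length(lines), length(platforms)),
                dimnames = list(ids, lines, platforms))
  for (p in profiles)
    cube[cbind(match(p$canonical_id, ids), match(p$cell_line, lines),
               match(p$platform, platforms))] <- p$detected
  cube
}

#' Percentile-rank cube matching a detection cube
#'
#' @param profiles list of `normalized_profile` data frames.
#' @param ids optional target axis (as in [call_detection()]).
#' @return numeric 3-d array `[id, cell_line, platform]` of percentile ranks,
#'   `NA` where not detected or not assayed.
#' @export
percentile_cube <- function(profiles, ids = NULL) {
  det <- call_detection(profiles, ids)
  pct <- array(NA_real_, dim = dim(det), dimnames = dimnames(det))
  dn <- dimnames(det)
  for (p in profiles)
    pct[cbind(match(p$canonical_id, dn[[1]]), match(p$cell_line, dn[[2]]),
              match(p$platform, dn[[3]]))] <- p$percentile
  pct
}

#' Label consensus truth from multi-platform detection
#'
#' A (miRNA, cell line) data point on the concordant panel is a *true
#' positive* when at least `min_platforms` platforms (default 3 of 4) detect
#' it, and a *true negative* otherwise. This consensus rule stands in for
#' unknowable molecular truth in biological samples: corroboration by
#' independent chemistries is the best available evidence of real presence.
#'
#' @param cube detection cube from [call_detection()].
#' @param concordant_ids canonical IDs assayed by all platforms (the panel on
#'   which truth is defined); must be a subset of the cube's target axis with
#'   no missing calls.
#' @param min_platforms detections required for a true positive (default 3).
#' @return Object of class `detection_truth`: list with `detection` (cube
#'   restricted to `concordant_ids`), `truth` (logical matrix id x line, TRUE
#'   = true positive), `n_points`, `n_true_positive`, `n_true_negative`,
#'   `min_platforms`.
#' @export
define_truth <- function(cube, concordant_ids, min_platforms = 3) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  if (dim(cube)[3] < min_platforms)
    stop("cube has fewer platforms than min_platforms")
  bad <- setdiff(concordant_ids, dimnames(cube)[[1]])
  if (length(bad))
    stop("concordant ids absent from the cube: ",
         paste(utils::head(bad, 5), collapse = ", "))
  det <- cube[concordant_ids, , , drop = FALSE]
  if (anyNA(det))
    stop("missing detection calls on the concordant panel")
  truth <- apply(det, c(1, 2), sum) >= min_platforms
  structure(list(detection = det, truth = truth,
                 n_points = length(truth),
                 n_true_positive = sum(truth),
                 n_true_negative = sum(!truth),
                 min_platforms = min_platforms),
            class = "detection_truth")
}

#' @export
print.detection_truth <- function(x, ...) {
  cat("detection_truth: ", x$n_points, " data points (",
      dim(x$detection)[1], " targets x ", dim(x$detection)[2],
      " cell lines), ", x$n_true_positive, " true positive (",
      round(100 * x$n_true_positive / x$n_points), "%), rule >= ",
      x$min_platforms, " of ", dim(x$detection)[3], " platforms\n", sep = "")
  invisible(x)
}

#' Sensitivity ratio from detection counts
#'
#' Sensitivity is the fraction of true-positive data points a platform
#' detects: detected true positives divided by all true positives.
#'
#' @param n_detected number of true positives detected by the platform.
#' @param n_true_positive total number of true positives.
#' @return list with `ratio`, `n_detected`, `n_true_positive`.
#' @examples
#' sensitivity_ratio(763, 777)$ratio  # 0.982 at 3 dp
#' @export
sensitivity_ratio <- function(n_detected, n_true_positive) {
  if (n_true_positive < 1) stop("sensitivity undefined: no true positives")
  stopifnot(n_detected >= 0, n_detected <= n_true_positive)
  list(ratio = n_detected / n_true_positive,
       n_detected = n_detected, n_true_positive = n_true_positive)
}

#' Platform sensitivity against the consensus truth
#' @param truth a [define_truth()] result.
#' @param platform platform name in the cube.
#' @return list with `ratio`, `n_detected`, `n_true_positive`.
#' @export
platform_sensitivity <- function(truth, platform) {
  stopifnot(inherits(truth, "detection_truth"))
  det <- truth_platform_slice(truth, platform)
  sensitivity_ratio(sum(det[truth$truth]), truth$n_true_positive)
}

#' Platform specificity against the consensus truth
#'
#' Specificity is the fraction of true-negative data points (detected by
#' fewer than `min_platforms` platforms) that the platform correctly does
#' not detect.
#'
#' @param truth a [define_truth()] result.
#' @param platform platform name in the cube.
#' @return list with `ratio`, `n_not_detected`, `n_true_negative`.
#' @export
platform_specificity <- function(truth, platform) {
  stopifnot(inherits(truth, "detection_truth"))
  if (truth$n_true_negative < 1)
    stop("specificity undefined: no true negatives")
  det <- truth_platform_slice(truth, platform)
  list(ratio = sum(!det[!truth$truth]) / truth$n_true_negative,
       n_not_detected = sum(!det[!truth$truth]),
       n_true_negative = truth$n_true_negative)
}

truth_platform_slice <- function(truth, platform) {
  platforms <- dimnames(truth$detection)[[3]]
  if (!platform %in% platforms)
    stop("unknown platform: ", platform)
  cube_slice(truth$detection, platform)
}
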