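#' Platform screening summary
#'
#' Per platform: the number of targeted miRNAs, how many were observed
#' (detected in at least one cell line), how many were observed in every
#' cell line, and the observed fraction of the platform panel and of the
#' full reference (nearest-integer percent, the reporting precision).
#'
#' @param panel a [reference_panel()] with platform panels declared.
#' @param cube detection cube from [call_detection()] (NA allowed off-panel).
#' @return data frame, one row per platform.
#' @export
panel_summary <- function(panel, cube) {
  stopifnot(inherits(panel, "reference_panel"))
  n_ref <- nrow(panel$targets)
  platforms <- dimnames(cube)[[3]]
  do.call(rbind, lapply(platforms, function(pl) {
    targeted <- panel$platform_panels[[pl]]
    det <- cube[intersect(targeted, dimnames(cube)[[1]]), , pl, drop = FALSE]
    obs <- apply(det, 1, function(v) any(v, na.rm = TRUE))
    obs_all <- apply(det, 1, function(v) all(!is.na(v)) && all(v))
    data.frame(platform = pl, targeted = length(targeted),
               observed = sum(obs), observed_all_lines = sum(obs_all),
               percent_of_targeted = round(100 * sum(obs) / length(targeted)),
               percent_of_reference = round(100 * sum(obs) / n_ref),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full cross-platform concordance analysis
#'
#' Executes every stage end-to-end: build (or accept) the reference panel
#' and per-platform measurement tables, normalize each platform
#' ([normalize_platform()]), assemble the detection cube and consensus truth
#' on the concordant panel ([define_truth()]), and compute the sensitivity/
#' specificity table, the pairwise concordance report, detection-overlap and
#' quintile-dispersion breakdowns, and all fold-change accuracy statistics.
#'
#' @param scenario simulation scenario (see [default_scenario()]); ignored
#'   when `tables` is supplied.
#' @param seed integer seed driving the simulation.
#' @param tables optional named list of [measurement_table()]s (real data
#'   path); requires `panel`.
#' @param panel optional [reference_panel()] matching `tables`.
#' @param cq_cutoff Cq detection cutoff applied during normalization.
#' @param min_reads minimum raw reads for NGS detection.
#' @param min_platforms platforms required for a true positive.
#' @param out_dir optional directory; when given, writes TSV reports and a
#'   machine-readable `summary.json` containing every reported number.
#' @param verbose log one line per stage.
#' @return list of class `concordance_run` with elements `profiles`, `cube`,
#'   `truth`, `sensitivity`, `pair_report`, `venn`, `venn_pooled`,
#'   `quintiles_single`, `quintiles_all`, `fold_changes`, `agreement`,
#'   `ap_by_magnitude`, `panel_summary`, `summary` (the JSON-ready list).
#' @export
run_concordance <- function(scenario = default_scenario(), seed = 1,
                            tables = NULL, panel = NULL, cq_cutoff = 36,
                            min_reads = 1, min_platforms = 3,
                            out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[mirconcord] ", ...)
  if (is.null(tables)) {
    sim <- simulate_scenario(scenario, seed)
    tables <- sim$tables
    panel <- sim$panel
    say("simulated ", length(tables), " platform tables, seed ", seed)
  } else if (is.null(panel)) {
    stop("supplying tables requires a reference panel")
  }

  profiles <- lapply(tables, normalize_platform, cq_cutoff = cq_cutoff,
                     min_reads = min_reads)
  say("normalized ", length(profiles), " platforms (cq_cutoff ", cq_cutoff,
      ", min_reads ", min_reads, ")")

  conc <- concordant_set(panel)
  cube <- call_detection(profiles)
  pct <- percentile_cube(profiles)
  truth <- define_truth(cube, conc, min_platforms)
  pct_conc <- pct[conc, , , drop = FALSE]
  say("concordant panel ", length(conc), " targets -> ", truth$n_points,
      " data points, ", truth$n_true_positive, " true positive (rule >= ",
      min_platforms, ")")

  platforms <- dimnames(cube)[[3]]
  # undefined ratios (no TP or no TN in the truth) are reported as NA
  sens <- do.call(rbind, lapply(platforms, function(pl) {
    s <- tryCatch(platform_sensitivity(truth, pl), error = function(e) NULL)
    sp <- tryCatch(platform_specificity(truth, pl), error = function(e) NULL)
    data.frame(platform = pl, n_true_positive = truth$n_true_positive,
               n_detected = if (is.null(s)) NA_integer_ else s$n_detected,
               sensitivity = if (is.null(s)) NA_real_ else round(s$ratio, 3),
               n_true_negative = truth$n_true_negative,
               n_not_detected = if (is.null(sp)) NA_integer_ else
                 sp$n_not_detected,
               specificity = if (is.null(sp)) NA_real_ else
                 round(sp$ratio, 3),
               stringsAsFactors = FALSE)
  }))
  if (truth$n_true_negative == 0)
    warning("no true negatives on the concordant panel; specificity undefined")
  pairs_tab <- pair_report(truth$detection, pct_conc)
  venn <- venn_counts(truth$detection, "data_point")
  venn_pooled <- venn_counts(truth$detection, "pooled")
  q_single <- quintile_dispersion(truth$detection, pct_conc, "single_platform")
  q_all <- quintile_dispersion(truth$detection, pct_conc, "all_platforms")
  say("pairwise concordance over ", nrow(pairs_tab), " platform pairs")

  records <- lapply(profiles, all_fold_changes)
  fc_all <- do.call(rbind, records)
  agreement <- list()
  for (pr in utils::combn(platforms, 2, simplify = FALSE)) {
    key <- paste(pr, collapse = "|")
    agreement[[key]] <- agreement_summary(records[[pr[1]]], records[[pr[2]]])
  }
  ap_mag <- if (length(platforms) >= 3)
    agreement_by_magnitude(records, mode = "AP") else NULL
  say("accuracy statistics over ", nrow(fc_all), " fold-change records")

  summary <- list(
    seed = seed,
    thresholds = list(cq_cutoff = cq_cutoff, min_reads = min_reads,
                      min_platforms = min_platforms),
    concordant_panel_size = length(conc),
    n_data_points = truth$n_points,
    n_true_positive = truth$n_true_positive,
    percent_true_positive = round(100 * truth$n_true_positive /
                                    truth$n_points),
    sensitivity = sens,
    pair_report = pairs_tab,
    venn = as.list(venn),
    venn_pooled = as.list(venn_pooled),
    quintiles_single_platform = q_single,
    quintiles_all_platforms = q_all,
    panel_summary = panel_summary(panel, cube),
    agreement = lapply(agreement, function(a) list(
      pair = a$pair, n = a$n, r = a$pearson$r, ci95 = a$pearson$ci95,
      p = a$pearson$p, sign_agreement_pct = a$sign_agreement_pct,
      by_percentile = a$by_percentile, by_magnitude = a$by_magnitude)),
    ap_by_magnitude = ap_mag)

  out <- structure(list(profiles = profiles, cube = cube, truth = truth,
                        percentiles = pct, sensitivity = sens,
                        pair_report = pairs_tab, venn = venn,
                        venn_pooled = venn_pooled,
                        quintiles_single = q_single, quintiles_all = q_all,
                        fold_changes = fc_all, agreement = agreement,
                        ap_by_magnitude = ap_mag,
                        panel_summary = summary$panel_summary,
                        summary = summary),
                   class = "concordance_run")
  if (!is.null(out_dir)) write_reports(out, out_dir)
  out
}

#' @export
print.concordance_run <- function(x, ...) {
  cat("concordance_run over", length(x$profiles), "platforms\n\n")
  cat("Sensitivity / specificity on the concordant panel:\n")
  print(x$sensitivity, row.names = FALSE)
  cat("\nPairwise concordance:\n")
  print(x$pair_report[, c("platform_a", "platform_b", "n_single", "n_both",
                          "percent_both", "weighted_score")],
        row.names = FALSE)
  invisible(x)
}

#' Write the report bundle of a concordance run
#'
#' Emits the human-readable TSV tables (panel summary, sensitivity/
#' specificity, pair report, detection-overlap counts, quintile dispersion,
#' fold changes, per-pair agreement) and `summary.json`, which contains
#' every number printed in the TSVs.
#'
#' @param run a [run_concordance()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(run, out_dir) {
  stopifnot(inherits(run, "concordance_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(run$panel_summary, "panel_summary.tsv")
  wt(run$sensitivity, "sensitivity.tsv")
  wt(run$pair_report, "pair_report.tsv")
  wt(data.frame(subset = names(run$venn), count = as.integer(run$venn)),
     "venn.tsv")
  q <- function(m, rule) data.frame(platform = rownames(m), rule = rule,
                                    m, check.names = FALSE)
  wt(rbind(q(run$quintiles_single, "single_platform"),
           q(run$quintiles_all, "all_platforms")), "quintile_dispersion.tsv")
  wt(run$fold_changes, "fold_changes.tsv")
  agg <- do.call(rbind, lapply(run$agreement, function(a) data.frame(
    platform_a = a$pair[1], platform_b = a$pair[2], n = a$n,
    r = a$pearson$r, ci_lo = a$pearson$ci95[1], ci_hi = a$pearson$ci95[2],
    p = a$pearson$p, sign_agreement_pct = a$sign_agreement_pct,
    stringsAsFactors = FALSE)))
  wt(agg, "agreement.tsv")
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
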