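#' Build a harmonized mature-miRNA reference panel
#'
#' A reference panel holds the canonical mature-miRNA targets shared across
#' profiling platforms. Source annotations that resolve to the same mature
#' sequence (the same ~22 nt molecule transcribed from different genomic
#' loci), or that a platform chemistry cannot tell apart, are collapsed to a
#' single canonical target whose `member_ids` record the merged source IDs.
#'
#' @param targets data frame with columns `canonical_id`, `members`
#'   (list-column of character vectors) and `sequence` (may be `NA`).
#' @param platform_panels named list of character vectors; for each platform,
#'   the canonical IDs that platform's assay targets. Must be subsets of
#'   `targets$canonical_id`.
#' @return An object of class `reference_panel`: a list with elements
#'   `targets`, `member_map` (named character vector, source ID ->
#'   canonical ID) and `platform_panels`.
#' @seealso [merge_reference()] which constructs the canonical targets,
#'   [concordant_set()], [map_assays()]
#' @export
reference_panel <- function(targets, platform_panels = list()) {
  stopifnot(is.data.frame(targets),
            all(c("canonical_id", "members", "sequence") %in% names(targets)))
  if (anyDuplicated(targets$canonical_id))
    stop("duplicate canonical_id in reference panel")
  member_map <- unlist(lapply(seq_len(nrow(targets)), function(i) {
    m <- targets$members[[i]]
    stats::setNames(rep(targets$canonical_id[i], length(m)), m)
  }))
  if (anyDuplicated(names(member_map)))
    stop("a member id maps to more than one canonical id")
  platform_panels <- lapply(platform_panels, function(p) sort(unique(p)))
  for (pl in names(platform_panels)) {
    bad <- setdiff(platform_panels[[pl]], targets$canonical_id)
    if (length(bad))
      stop("platform panel '", pl, "' contains ids absent from the reference: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(targets = targets, member_map = member_map,
                 platform_panels = platform_panels),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", nrow(x$targets), "canonical targets,",
      length(x$member_map), "member ids\n")
  for (pl in names(x$platform_panels))
    cat("  panel", pl, ":", length(x$platform_panels[[pl]]), "targets\n")
  invisible(x)
}

#' Merge source miRNA annotations into canonical targets
#'
#' Collapses raw target annotations into canonical targets by two rules:
#' targets with identical (non-missing) mature sequence are merged, and every
#' explicitly supplied merge group (e.g. assays a platform cannot
#' distinguish, such as close paralog families) is collapsed to one target.
#' Merging is transitive: overlapping groups are unioned rather than
#' rejected. The canonical ID of a merged group is the lexicographically
#' smallest member ID, so merging is deterministic and reversible through
#' `member_ids`.
#'
#' @param raw_targets data frame with columns `id` and `sequence`
#'   (`NA` sequence allowed; missing sequences never trigger a merge).
#' @param merge_groups list of character vectors, each naming `id`s to
#'   collapse into one canonical target.
#' @param platform_panels optional named list of character vectors of *source*
#'   IDs per platform; they are translated to canonical IDs in the result.
#' @return A [reference_panel()].
#' @examples
#' raw <- data.frame(id = c("a", "b", "c"),
#'                   sequence = c("UGAGG", "UGAGG", "ACCCA"))
#' merge_reference(raw)$targets$canonical_id
#' @export
merge_reference <- function(raw_targets, merge_groups = list(),
                            platform_panels = list()) {
  stopifnot(is.data.frame(raw_targets),
            all(c("id", "sequence") %in% names(raw_targets)))
  ids <- as.character(raw_targets$id)
  if (anyDuplicated(ids))
    stop("raw target ids are not unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(raw_targets$sequence)

  # union-find over ids; roots indexed by position
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- max(ri, rj)
    invisible(NULL)
  }

  # rule 1: identical mature sequence
  has_seq <- !is.na(seqs) & nzchar(seqs)
  for (s in unique(seqs[has_seq])) {
    idx <- which(has_seq & seqs == s)
    if (length(idx) > 1) for (k in idx[-1]) union_(idx[1], k)
  }
  # rule 2: explicit merge groups (platform indistinguishability)
  for (g in merge_groups) {
    g <- as.character(g)
    unknown <- setdiff(g, ids)
    if (length(unknown))
      stop("merge group names unknown id(s): ",
           paste(unknown, collapse = ", "))
    idx <- match(g, ids)
    if (length(idx) > 1) for (k in idx[-1]) union_(idx[1], k)
  }

  root <- vapply(seq_along(ids), find, integer(1))
  groups <- split(seq_along(ids), root)
  targets <- do.call(rbind, lapply(groups, function(idx) {
    members <- sort(ids[idx])
    sq <- unique(seqs[idx][!is.na(seqs[idx])])
    data.frame(canonical_id = members[1],
               members = I(list(members)),
               sequence = if (length(sq) == 1) sq else NA_character_,
               stringsAsFactors = FALSE)
  }))
  targets <- targets[order(targets$canonical_id), , drop = FALSE]
  rownames(targets) <- NULL

  panel <- reference_panel(targets)
  if (length(platform_panels)) {
    canon <- lapply(platform_panels, function(p) {
      unknown <- setdiff(p, ids)
      if (length(unknown))
        stop("platform panel names unknown id(s): ",
             paste(unknown, collapse = ", "))
      unique(unname(panel$member_map[p]))
    })
    panel <- reference_panel(targets, canon)
  }
  panel
}

#' Concordant target set across platforms
#'
#' The concordant set is the intersection of the canonical targets assayed by
#' every named platform — the only targets on which all platforms can be
#' compared fairly. An empty intersection is legal but is reported with a
#' warning because every downstream consensus statistic would be undefined.
#'
#' @param panel a [reference_panel()].
#' @param platforms character vector of platform names; default all declared.
#' @return Sorted character vector of canonical IDs.
#' @export
concordant_set <- function(panel, platforms = names(panel$platform_panels)) {
  stopifnot(inherits(panel, "reference_panel"))
  unknown <- setdiff(platforms, names(panel$platform_panels))
  if (length(unknown))
    stop("unknown platform(s): ", paste(unknown, collapse = ", "))
  out <- Reduce(intersect, panel$platform_panels[platforms])
  if (!length(out))
    warning("concordant set is empty for platforms: ",
            paste(platforms, collapse = ", "))
  sort(out)
}

#' Map platform assay IDs onto canonical targets
#'
#' Assay IDs present in a measurement table are translated to canonical IDs
#' through the panel's member map. IDs absent from the reference (obsolete or
#' withdrawn annotations) are returned in a `discarded` bucket, never
#' silently dropped: every input ID lands in exactly one of
#' `mapping`/`discarded`.
#'
#' @param assay_ids character vector of assay IDs from a platform table.
#' @param panel a [reference_panel()].
#' @return list with `mapping` (named character vector assay ID ->
#'   canonical ID) and `discarded` (character vector).
#' @export
map_assays <- function(assay_ids, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  assay_ids <- as.character(assay_ids)
  hit <- assay_ids %in% names(panel$member_map)
  list(mapping = panel$member_map[assay_ids[hit]],
       discarded = assay_ids[!hit])
}

#' Collapse assay-level rows of a value matrix onto canonical targets
#'
#' When two assays map to the same canonical target (a merged target), their
#' measurements must be combined: count-like units are summed (preserving
#' total signal), Cq values take the per-sample minimum (the strongest
#' signal, preserving detection status). Missing Cq values are ignored in
#' the minimum; an all-missing group stays missing.
#'
#' @param values numeric matrix, rows named by assay ID.
#' @param mapping named character vector assay ID -> canonical ID (e.g. from
#'   [map_assays()]); rows not named in it are dropped.
#' @param unit_kind one of `"read_count"`, `"probe_count"` (sum) or `"cq"`
#'   (minimum).
#' @return numeric matrix with one row per canonical ID.
#' @export
collapse_assays <- function(values, mapping,
                            unit_kind = c("read_count", "probe_count", "cq")) {
  unit_kind <- match.arg(unit_kind)
  keep <- rownames(values) %in% names(mapping)
  values <- values[keep, , drop = FALSE]
  canon <- unname(mapping[rownames(values)])
  ids <- sort(unique(canon))
  out <- matrix(NA_real_, length(ids), ncol(values),
                dimnames = list(ids, colnames(values)))
  for (id in ids) {
    rows <- values[canon == id, , drop = FALSE]
    out[id, ] <- if (unit_kind == "cq") {
      apply(rows, 2, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    } else {
      colSums(rows)
    }
  }
  out
}

#' Read a reference TSV (id <TAB> sequence, one header line)
#' @param path file path.
#' @return data frame with columns `id`, `sequence`.
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  names(df)[1:2] <- c("id", "sequence")
  df
}

#' Read a merge-group TSV (group_id <TAB> member_id, one header line)
#' @param path file path.
#' @return list of character vectors, one per group.
#' @export
read_merge_groups_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  names(df)[1:2] <- c("group_id", "member_id")
  unname(split(df$member_id, df$group_id))
}

#' Read a platform-panel TSV (platform <TAB> canonical_id, one header line)
#' @param path file path.
#' @return named list of character vectors, one per platform.
#' @export
read_platform_panels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  names(df)[1:2] <- c("platform", "canonical_id")
  split(df$canonical_id, df$platform)
}
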