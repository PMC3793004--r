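# Independent brute-force oracles: plain per-point loops, no shared code with
# the implementation.

random_cube <- function(n_ids = 30, n_lines = 3,
                        platforms = c("P1", "P2", "P3", "P4"),
                        prob = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("m%03d", seq_len(n_ids))
  lines <- paste0("L", seq_len(n_lines))
  array(stats::rbinom(n_ids * n_lines * length(platforms), 1, prob) == 1,
        dim = c(n_ids, n_lines, length(platforms)),
        dimnames = list(ids, lines, platforms))
}

# percentile ranks consistent with a cube: detected entries ranked by a
# random latent value within each (line, platform)
random_pct <- function(cube, seed = 2) {
  set.seed(seed)
  pct <- array(NA_real_, dim = dim(cube), dimnames = dimnames(cube))
  for (l in seq_len(dim(cube)[2])) for (p in seq_len(dim(cube)[3])) {
    det <- which(cube[, l, p])
    if (length(det))
      pct[det, l, p] <- sample(seq_along(det)) / length(det)
  }
  pct
}

oracle_truth_labels <- function(cube, min_platforms = 3) {
  dn <- dimnames(cube)
  truth <- matrix(NA, dim(cube)[1], dim(cube)[2], dimnames = dn[1:2])
  for (i in seq_len(dim(cube)[1])) for (j in seq_len(dim(cube)[2])) {
    n <- 0
    for (p in seq_len(dim(cube)[3])) if (cube[i, j, p]) n <- n + 1
    truth[i, j] <- n >= min_platforms
  }
  truth
}

oracle_sensitivity <- function(cube, truth, platform) {
  det <- 0; tot <- 0
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
    if (truth[i, j]) {
      tot <- tot + 1
      if (cube[i, j, platform]) det <- det + 1
    }
  }
  c(detected = det, total = tot, ratio = det / tot)
}

oracle_specificity <- function(cube, truth, platform) {
  nd <- 0; tot <- 0
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
    if (!truth[i, j]) {
      tot <- tot + 1
      if (!cube[i, j, platform]) nd <- nd + 1
    }
  }
  c(not_detected = nd, total = tot, ratio = nd / tot)
}

oracle_pair_counts <- function(cube, pair) {
  platforms <- dimnames(cube)[[3]]
  others <- setdiff(platforms, pair)
  counts <- c(minus = 0, minus2 = 0, minus3 = 0,
              plus = 0, plus2 = 0, plus3 = 0)
  for (i in seq_len(dim(cube)[1])) for (j in seq_len(dim(cube)[2])) {
    a <- cube[i, j, pair[1]]; b <- cube[i, j, pair[2]]
    if (!a && !b) next
    k <- sum(cube[i, j, others])
    bucket <- if (a && b) 3 + k + 1 else k + 1
    counts[bucket] <- counts[bucket] + 1
  }
  counts
}

oracle_weighted_score <- function(cube, pct, pair) {
  platforms <- dimnames(cube)[[3]]
  others <- setdiff(platforms, pair)
  num <- 0; den <- 0; n <- 0
  for (i in seq_len(dim(cube)[1])) for (j in seq_len(dim(cube)[2])) {
    a <- cube[i, j, pair[1]]; b <- cube[i, j, pair[2]]
    if (!a && !b) next
    n <- n + 1
    detp <- platforms[cube[i, j, ]]
    p_m <- mean(pct[i, j, detp])
    k <- sum(cube[i, j, others])
    w <- p_m * (1 + k) / 3
    s <- if (a && b) 1 else -1
    num <- num + s * w; den <- den + w
  }
  if (n == 0) NA_real_ else num / den
}

oracle_venn <- function(cube) {
  platforms <- dimnames(cube)[[3]]
  out <- list()
  for (i in seq_len(dim(cube)[1])) for (j in seq_len(dim(cube)[2])) {
    sub <- platforms[cube[i, j, ]]
    if (!length(sub)) next
    key <- paste(sub, collapse = "+")
    out[[key]] <- (out[[key]] %||% 0) + 1
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_quintiles <- function(cube, pct, platform, rule) {
  platforms <- dimnames(cube)[[3]]
  vals <- c()
  for (i in seq_len(dim(cube)[1])) for (j in seq_len(dim(cube)[2])) {
    ndet <- sum(cube[i, j, ])
    ok <- if (rule == "single_platform")
      cube[i, j, platform] && ndet == 1 else ndet == length(platforms)
    if (ok) vals <- c(vals, pct[i, j, platform])
  }
  if (!length(vals)) return(rep(NA_real_, 5))
  bins <- pmin(floor(vals * 5) + 1, 5)
  sapply(1:5, function(b) sum(bins == b)) / length(vals)
}

# profiles for a platform built directly from chosen linear values
profile_from_linear <- function(platform, linear_by_line) {
  do.call(rbind, lapply(names(linear_by_line), function(cl) {
    v <- linear_by_line[[cl]]
    detected <- v > 0
    pct <- rep(NA_real_, length(v))
    if (any(detected))
      pct[detected] <- rank(v[detected], ties.method = "average") /
        sum(detected)
    data.frame(platform = platform, canonical_id = names(v), cell_line = cl,
               linear = v, log2 = ifelse(v > 0, log2(v), NA), detected = detected,
               percentile = pct, stringsAsFactors = FALSE, row.names = NULL)
  }))
}
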