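two_line_profiles <- function(seed = 1, n = 12, platforms = c("A", "B"),
                              noise_sd = 0, lines = c("X", "Y")) {
  set.seed(seed)
  ids <- sprintf("m%02d", seq_len(n))
  base <- setNames(2^runif(n, 2, 10), ids)
  fc <- setNames(rnorm(n, 0, 1.5), ids)
  lapply(setNames(platforms, platforms), function(p) {
    profile_from_linear(p, setNames(lapply(lines, function(l) {
      v <- if (l == lines[1]) base * 2^fc else base
      v * 2^rnorm(n, 0, noise_sd)
    }), lines))
  })
}

test_that("fold changes are log2 ratios over both-detected targets", {
  prof <- profile_from_linear("A", list(X = c(m1 = 8, m2 = 4, m3 = 0),
                                        Y = c(m1 = 2, m2 = 4, m3 = 5)))
  fc <- fold_changes(prof, c("X", "Y"))
  expect_equal(fc$canonical_id, c("m1", "m2"))  # m3 undetected in X
  expect_equal(fc$log2_fc, c(2, 0))
  expect_equal(fc$base_percentile,
               (prof$percentile[prof$cell_line == "X"][1:2] +
                  prof$percentile[prof$cell_line == "Y"][1:2]) / 2)
  # swapping the pair negates the fold change exactly
  rev_fc <- fold_changes(prof, c("Y", "X"))
  expect_equal(rev_fc$log2_fc, -fc$log2_fc)
  expect_error(fold_changes(prof, c("X", "Z")), "Z")
})

test_that("a detected flag with zero linear value is an error", {
  prof <- profile_from_linear("A", list(X = c(m1 = 8), Y = c(m1 = 2)))
  prof$linear[1] <- 0  # corrupt: detected but zero
  expect_error(fold_changes(prof, c("X", "Y")), "detected")
})

test_that("all_fold_changes covers every cell-line pair once", {
  prof <- profile_from_linear("A", list(X = c(m1 = 8, m2 = 2),
                                        Y = c(m1 = 4, m2 = 2),
                                        Z = c(m1 = 2, m2 = 2)))
  fc <- all_fold_changes(prof)
  expect_equal(sort(unique(fc$line_pair)), c("X/Y", "X/Z", "Y/Z"))
  expect_equal(nrow(fc), 6)
})

test_that("pearson r and CI match an independent Fisher-z computation", {
  profs <- two_line_profiles(seed = 7, n = 10, noise_sd = 0.4)
  ra <- all_fold_changes(profs$A)
  rb <- all_fold_changes(profs$B)
  got <- pearson_log2fc(ra, rb)
  # independent oracle on the merged vectors
  key <- paste(ra$canonical_id, ra$line_pair)
  keyb <- paste(rb$canonical_id, rb$line_pair)
  shared <- intersect(key, keyb)
  x <- ra$log2_fc[match(shared, key)]
  y <- rb$log2_fc[match(shared, keyb)]
  n <- length(shared)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$ci95, ci, tolerance = 1e-12)
  expect_equal(got$p, p, tolerance = 1e-12)
  expect_equal(got$n, n)
  # identical / negated records
  expect_equal(pearson_log2fc(ra, ra)$r, 1)
  neg <- ra; neg$log2_fc <- -neg$log2_fc
  expect_equal(pearson_log2fc(ra, neg)$r, -1)
  expect_error(pearson_log2fc(ra[1:2, ], rb[1:2, ]), "3")
})

test_that("pearson is symmetric and shift-invariant", {
  profs <- two_line_profiles(seed = 8, n = 15, noise_sd = 0.3)
  ra <- all_fold_changes(profs$A)
  rb <- all_fold_changes(profs$B)
  expect_equal(pearson_log2fc(ra, rb)$r, pearson_log2fc(rb, ra)$r)
  shift_a <- ra; shift_a$log2_fc <- shift_a$log2_fc + 3
  shift_b <- rb; shift_b$log2_fc <- shift_b$log2_fc + 3
  expect_equal(pearson_log2fc(shift_a, shift_b)$r,
               pearson_log2fc(ra, rb)$r, tolerance = 1e-12)
})

test_that("sign agreement counts matching directions, ties agree", {
  ra <- data.frame(canonical_id = sprintf("m%d", 1:10), line_pair = "X/Y",
                   platform = "A",
                   log2_fc = c(1, -1, 2, -2, 0, 1, -1, 3, -3, 0.5),
                   base_percentile = 0.5)
  rb <- ra
  rb$platform <- "B"
  rb$log2_fc <- c(2, -2, -1, 1, 5, 0, -0.5, 2, 3, -0.5)
  # manual count: agree at 1,2,5(tie),6(tie),7,8 -> 6 of 10, plus
  # disagree at 3,4,9,10
  expect_equal(sign_agreement(ra, rb)$percent, 60)
  expect_equal(sign_agreement(ra, ra)$percent, 100)
  opp <- ra; opp$log2_fc <- -opp$log2_fc; opp$log2_fc[opp$log2_fc == 0] <- 1e9
  ra2 <- ra; ra2$log2_fc[ra2$log2_fc == 0] <- -1e9
  expect_equal(sign_agreement(ra2, opp)$percent, 0)
})

test_that("reversing line-pair orientation leaves agreement unchanged", {
  profs <- two_line_profiles(seed = 9, n = 20, noise_sd = 0.5)
  ra <- fold_changes(profs$A, c("X", "Y"))
  rb <- fold_changes(profs$B, c("X", "Y"))
  ra_rev <- fold_changes(profs$A, c("Y", "X"))
  rb_rev <- fold_changes(profs$B, c("Y", "X"))
  ra_rev$line_pair <- ra$line_pair[match(ra_rev$canonical_id, ra$canonical_id)]
  rb_rev$line_pair <- rb$line_pair[match(rb_rev$canonical_id, rb$canonical_id)]
  expect_equal(sign_agreement(ra, rb)$percent,
               sign_agreement(ra_rev, rb_rev)$percent)
  expect_equal(pearson_log2fc(ra, rb)$r, pearson_log2fc(ra_rev, rb_rev)$r,
               tolerance = 1e-12)
})

test_that("percentile-binned agreement matches direct tabulation", {
  profs <- two_line_profiles(seed = 10, n = 40, noise_sd = 0.6)
  ra <- all_fold_changes(profs$A)
  rb <- all_fold_changes(profs$B)
  got <- agreement_by_percentile(ra, rb)
  # direct tabulation oracle
  key <- paste(ra$canonical_id, ra$line_pair)
  keyb <- paste(rb$canonical_id, rb$line_pair)
  shared <- intersect(key, keyb)
  ia <- match(shared, key); ib <- match(shared, keyb)
  pct <- (ra$base_percentile[ia] + rb$base_percentile[ib]) / 2
  agree <- ra$log2_fc[ia] == 0 | rb$log2_fc[ib] == 0 |
    sign(ra$log2_fc[ia]) == sign(rb$log2_fc[ib])
  for (b in 1:5) {
    sel <- pct >= (b - 1) / 5 & (pct < b / 5 | b == 5)
    if (any(sel)) expect_equal(got$percent[b], 100 * mean(agree[sel]))
    expect_equal(got$n[b], sum(sel))
  }
  # noiseless identical data: 100% in every occupied bin
  ident <- agreement_by_percentile(ra, ra)
  expect_true(all(ident$percent[ident$n > 0] == 100))
})

test_that("magnitude-binned agreement: trivials, oracle, and AP contract", {
  profs <- two_line_profiles(seed = 11, n = 30, noise_sd = 0.5,
                             platforms = c("A", "B", "C"))
  recs <- lapply(profs, all_fold_changes)
  ident <- agreement_by_magnitude(list(recs$A, recs$A), "Paired")
  expect_true(all(ident$percent[ident$n > 0] == 100))
  flip <- recs$A
  flip$log2_fc <- -flip$log2_fc - 1e-9   # avoid 0 ties
  flipped <- agreement_by_magnitude(list(recs$A, flip), "Paired")
  expect_true(all(flipped$percent[flipped$n > 0] == 0))
  expect_error(agreement_by_magnitude(recs, "Paired"), "2")
  expect_error(agreement_by_magnitude(recs[1:2], "AP"), "3")

  # oracle for Paired on two platforms
  got <- agreement_by_magnitude(list(recs$A, recs$B), "Paired")
  key <- paste(recs$A$canonical_id, recs$A$line_pair)
  keyb <- paste(recs$B$canonical_id, recs$B$line_pair)
  shared <- intersect(key, keyb)
  fa <- recs$A$log2_fc[match(shared, key)]
  fb <- recs$B$log2_fc[match(shared, keyb)]
  mag <- (abs(fa) + abs(fb)) / 2
  agree <- fa == 0 | fb == 0 | sign(fa) == sign(fb)
  edges <- c(0, 0.585, 1, 1.585, Inf)
  for (b in 1:4) {
    sel <- mag >= edges[b] & mag < edges[b + 1]
    expect_equal(got$n[b], sum(sel))
    if (any(sel)) expect_equal(got$percent[b], 100 * mean(agree[sel]))
  }

  # AP mode: all platforms must share the direction of the mean
  ap <- agreement_by_magnitude(recs, "AP")
  keyc <- paste(recs$C$canonical_id, recs$C$line_pair)
  shared3 <- Reduce(intersect, list(key, keyb, keyc))
  f3 <- cbind(recs$A$log2_fc[match(shared3, key)],
              recs$B$log2_fc[match(shared3, keyb)],
              recs$C$log2_fc[match(shared3, keyc)])
  mag3 <- rowMeans(abs(f3))
  agr3 <- apply(f3, 1, function(v) {
    mu <- mean(v); all(v == 0 | mu == 0 | sign(v) == sign(mu))
  })
  for (b in 1:4) {
    sel <- mag3 >= edges[b] & mag3 < edges[b + 1]
    expect_equal(ap$n[b], sum(sel))
    if (any(sel)) expect_equal(ap$percent[b], 100 * mean(agr3[sel]))
  }
})

test_that("magnitude-bin agreement trends upward under symmetric noise", {
  # average over 20 seeded replicates: expected agreement rises with |FC|;
  # per-line noise 0.35 gives each platform's fold change a noise sd near
  # 0.5 on the log2 scale
  bins <- matrix(NA_real_, 20, 4)
  for (s in 1:20) {
    profs <- two_line_profiles(seed = 1000 + s, n = 60, noise_sd = 0.35)
    got <- agreement_by_magnitude(
      list(all_fold_changes(profs$A), all_fold_changes(profs$B)), "Paired")
    bins[s, ] <- got$percent
  }
  avg <- colMeans(bins, na.rm = TRUE)
  expect_true(all(diff(avg) > -1e-9))
  expect_gte(avg[4], 98)
})

test_that("agreement_summary bundles the pairwise statistics", {
  profs <- two_line_profiles(seed = 13, n = 25, noise_sd = 0.4)
  s <- agreement_summary(all_fold_changes(profs$A), all_fold_changes(profs$B))
  expect_s3_class(s, "agreement_summary")
  expect_equal(s$pair, c("A", "B"))
  expect_true(abs(s$pearson$r) <= 1)
  expect_true(s$pearson$ci95[1] <= s$pearson$r &&
                s$pearson$r <= s$pearson$ci95[2])
  expect_true(s$sign_agreement_pct >= 0 && s$sign_agreement_pct <= 100)
})
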