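test_that("truth generation is seed-deterministic and validates inputs", {
  t1 <- generate_truth(n_mirna = 50, seed = 123)
  t2 <- generate_truth(n_mirna = 50, seed = 123)
  expect_identical(t1, t2)
  t3 <- generate_truth(n_mirna = 50, seed = 124)
  expect_false(identical(t1$baseline_log2, t3$baseline_log2))
  expect_error(generate_truth(de_fraction = 1.5), "de_fraction")
  expect_error(generate_truth(effect_range_log2 = c(2, 1)), "effect_range")
})

test_that("DE bookkeeping is exact and zero DE means all fold changes 1", {
  tr <- generate_truth(n_mirna = 1000, de_fraction = 0.2,
                       expressed_fraction = 1, seed = 5)
  expect_equal(length(tr$de_ids), 200)
  expect_true(all(tr$de_spec[setdiff(tr$ids, tr$de_ids), ] == 0))
  tr0 <- generate_truth(n_mirna = 100, de_fraction = 0, seed = 5)
  expect_true(all(tr0$de_spec == 0))
  # true fold change is effect difference, bias-free
  tr2 <- generate_truth(n_mirna = 100, de_fraction = 0.5,
                        expressed_fraction = 1, seed = 6)
  fc <- tr2$de_spec[, "lineB"] - tr2$de_spec[, "lineC"]
  expect_true(all(is.finite(fc)))
})

test_that("unexpressed targets have zero abundance everywhere", {
  tr <- generate_truth(n_mirna = 200, expressed_fraction = 0.4, seed = 7)
  expect_equal(length(tr$expressed_ids), 80)
  off <- setdiff(tr$ids, tr$expressed_ids)
  expect_true(all(tr$baseline_log2[off] == -Inf))
  expect_true(all(tr$de_spec[off, ] == 0))
  tab <- simulate_ngs(tr, "solid", depth = 1e4, seed = 8, n_replicates = 1)
  expect_true(all(tab$values[off, ] == 0))
})

test_that("NGS totals concentrate around depth (Poisson sum property)", {
  tr <- generate_truth(n_mirna = 100, expressed_fraction = 1, seed = 9)
  depth <- 1e4
  hits <- 0
  for (s in 1:20) {
    tab <- simulate_ngs(tr, "solid", depth = depth, n_replicates = 1,
                        seed = 100 + s)
    tot <- colSums(tab$values)
    hits <- hits + sum(abs(tot - depth) <= 3 * sqrt(depth))
  }
  # 20 seeds x 4 lines; 3-sigma misses are ~0.3% per sample
  expect_gte(hits, 78)
  expect_error(simulate_ngs(tr, "solid", depth = 0), "depth")
  # deterministic mode returns expectations exactly
  det <- simulate_ngs(tr, "solid", depth = depth, n_replicates = 1,
                      seed = 1, noise = FALSE)
  expect_equal(unname(colSums(det$values)), rep(depth, 4))
})

test_that("seeded tables are bit-identical across calls", {
  tr <- generate_truth(n_mirna = 40, seed = 11)
  expect_identical(simulate_ngs(tr, "solid", seed = 3),
                   simulate_ngs(tr, "solid", seed = 3))
  expect_identical(simulate_qpcr(tr, "mircury", seed = 3),
                   simulate_qpcr(tr, "mircury", seed = 3))
  expect_identical(simulate_hyb(tr, "ncounter", seed = 3),
                   simulate_hyb(tr, "ncounter", seed = 3))
})

test_that("noise-free qPCR encodes abundance exactly on the Cq scale", {
  tr <- generate_truth(n_mirna = 30, de_fraction = 0.5,
                       expressed_fraction = 1, bias_sd_log2 = 0,
                       baseline_mean_log2 = 10, baseline_sd_log2 = 1,
                       seed = 13)
  tab <- simulate_qpcr(tr, "mircury", c0 = 34, noise_sd = 0, cutoff = 36,
                       n_replicates = 1, seed = 14)
  # doubling of abundance shifts Cq by exactly -1
  cqA <- tab$values[, "lineA.1"]
  cqB <- tab$values[, "lineB.1"]
  expect_equal(cqA - cqB, tr$de_spec[, "lineB"] - tr$de_spec[, "lineA"])
  # recovered fold change through the full pipeline equals the truth
  prof <- normalize_platform(tab)
  fc <- fold_changes(prof, c("lineB", "lineA"))
  truth_fc <- tr$de_spec[fc$canonical_id, "lineB"] -
    tr$de_spec[fc$canonical_id, "lineA"]
  # total-count scaling adds one shared per-pair constant
  expect_equal(unname(fc$log2_fc - mean(fc$log2_fc - truth_fc)),
               unname(truth_fc), tolerance = 1e-9)
  # censoring: abundances below the cutoff margin go missing
  tabc <- simulate_qpcr(tr, "mircury", c0 = 50, noise_sd = 0, cutoff = 36,
                        n_replicates = 1, seed = 15)
  should_censor <- (50 - tr$baseline_log2 - tr$de_spec[, "lineA"]) >= 36
  expect_equal(unname(is.na(tabc$values[, "lineA.1"])),
               unname(should_censor))
  expect_error(simulate_qpcr(tr, "mircury", noise_sd = -1), "noise_sd")
})

test_that("hybridization controls behave and efficiency is removable", {
  tr <- generate_truth(n_mirna = 40, expressed_fraction = 1,
                       baseline_mean_log2 = 8, baseline_sd_log2 = 1.5,
                       seed = 17)
  tab <- simulate_hyb(tr, "ncounter", gain = 1, bg_mean = 0, bg_sd = 0,
                      efficiency_sd_log2 = 0.5, n_replicates = 2, seed = 18)
  expect_equal(dim(tab$positive_spikes), c(6L, 8L))
  expect_equal(dim(tab$negative_probes), c(8L, 8L))
  # spike normalization removes the per-sample efficiency factor
  norm <- spike_normalize(tab)
  ratio <- norm$values[, "lineA.1"] / norm$values[, "lineA.2"]
  expect_equal(unname(ratio), rep(1, 40), tolerance = 1e-6)
  expect_error(simulate_hyb(tr, "ncounter", bg_mean = -1), "background")
  expect_error(simulate_hyb(tr, "ncounter", spike_levels = 1:3), "6")
})

test_that("gain 0 makes hybridization targets indistinguishable from background", {
  tr <- generate_truth(n_mirna = 30, expressed_fraction = 1, seed = 19)
  tab <- simulate_hyb(tr, "ncounter", gain = 0, bg_mean = 10, bg_sd = 4,
                      n_replicates = 3, seed = 20)
  cor <- subtract_background(tab)
  # background mean + 2 sd cuts ~97.7% of pure-noise values per replicate;
  # majority-of-3 detection then passes almost nothing
  det_rep <- cor$values > 0
  det <- sapply(unique(cor$samples$cell_line), function(cl)
    rowMeans(det_rep[, cor$samples$cell_line == cl, drop = FALSE]) > 0.5)
  expect_lt(mean(det), 0.05)
})

test_that("low-abundance dropout frequency tracks the background model", {
  # targets at fixed abundance a survive background correction iff
  # gain*a + background noise exceeds the estimated mean + 2 sd threshold
  # from 8 negatives; the oracle simulates that normal model directly
  gain <- 1; bg_mean <- 20; bg_sd <- 5; ab_log2 <- 3
  tr <- generate_truth(n_mirna = 200, expressed_fraction = 1,
                       baseline_mean_log2 = ab_log2, baseline_sd_log2 = 0,
                       de_fraction = 0, bias_sd_log2 = 0, seed = 21)
  rate <- numeric(20)
  for (s in 1:20) {
    tab <- simulate_hyb(tr, "ncounter", gain = gain, bg_mean = bg_mean,
                        bg_sd = bg_sd, efficiency_sd_log2 = 0,
                        n_replicates = 1, seed = 200 + s)
    cor <- subtract_background(tab)
    rate[s] <- mean(cor$values > 0)
  }
  set.seed(999)
  oracle <- mean(replicate(2e4, {
    negs <- pmax(rnorm(8, bg_mean, bg_sd), 0)
    thr <- mean(negs) + 2 * sd(negs)
    val <- max(0, gain * 2^ab_log2 + bg_mean + rnorm(1, 0, bg_sd))
    val > thr
  }))
  expect_lt(abs(mean(rate) - oracle), 0.03)
})

test_that("raising hybridization background depresses sensitivity and scores", {
  sens <- numeric(0)
  score <- numeric(0)
  for (bg in c(2, 10, 30)) {
    s_acc <- 0; w_acc <- 0
    for (s in 1:3) {
      sc <- default_scenario(n_mirna = 120, n_core = 80,
                             expressed_fraction = 0.7)
      sc$platforms$ncounter$bg_mean <- bg
      run <- suppressWarnings(run_concordance(sc, seed = 300 + s))
      s_acc <- s_acc + run$sensitivity$sensitivity[
        run$sensitivity$platform == "ncounter"]
      w_acc <- w_acc + mean(run$pair_report$weighted_score[
        run$pair_report$platform_a == "ncounter" |
          run$pair_report$platform_b == "ncounter"])
    }
    sens <- c(sens, s_acc / 3)
    score <- c(score, w_acc / 3)
  }
  expect_true(all(diff(sens) < 0))
  expect_true(all(diff(score) < 0))
})

test_that("matched NGS platforms recover large effects at depth", {
  tr <- generate_truth(n_mirna = 150, de_fraction = 0.4,
                       expressed_fraction = 1, bias_sd_log2 = 1, seed = 23)
  ta <- simulate_ngs(tr, "solid", depth = 1e6, n_replicates = 1, seed = 24)
  tb <- simulate_ngs(tr, "illumina", depth = 1e6, n_replicates = 1, seed = 25)
  fa <- all_fold_changes(normalize_platform(ta))
  fb <- all_fold_changes(normalize_platform(tb))
  key <- paste(fa$canonical_id, fa$line_pair)
  keyb <- paste(fb$canonical_id, fb$line_pair)
  shared <- intersect(key, keyb)
  big <- abs(fa$log2_fc[match(shared, key)]) >= 2
  agree <- sign(fa$log2_fc[match(shared, key)]) ==
    sign(fb$log2_fc[match(shared, keyb)])
  expect_gte(mean(agree[big]), 0.98)
})

test_that("scenario simulation is deterministic and correctly shaped", {
  sc <- default_scenario(n_mirna = 80, n_core = 50)
  a <- simulate_scenario(sc, seed = 42)
  b <- simulate_scenario(sc, seed = 42)
  expect_identical(a$tables, b$tables)
  expect_equal(length(a$tables), 4)
  expect_equal(length(concordant_set(a$panel)), 50)
  expect_equal(nrow(a$tables$solid$values), 80)
  expect_equal(nrow(a$tables$mircury$values),
               length(a$panel$platform_panels$mircury))
  expect_equal(a$tables$ncounter$unit_kind, "probe_count")
  expect_equal(ncol(a$tables$illumina$values), 4)   # single replicate
  expect_equal(ncol(a$tables$mircury$values), 12)   # triplicate
})
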