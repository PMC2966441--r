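test_that("T-statistic ranking matches the pooled two-sample oracle", {
  # hand-checkable voxel: condA [1,2,3], condB [4,5,6] -> |T| = 3.674
  x <- cbind(c(1, 2, 3, 4, 5, 6), rnorm(6))
  meta <- data.frame(condition = rep(c("L_low", "R_low"), each = 3),
                     run = 1:6, stringsAsFactors = FALSE)
  smp <- pattern_samples(x, meta)
  t_abs <- utrocular:::abs_tstat(x[1:3, , drop = FALSE], x[4:6, , drop = FALSE])
  expect_equal(t_abs[1], abs(oracle_two_sample_t(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-12)
  expect_equal(round(t_abs[1], 3), 3.674)
  # randomized instances against the oracle
  set.seed(20)
  for (i in 1:25) {
    xa <- matrix(rnorm(5 * 8), 5, 8)
    xb <- matrix(rnorm(7 * 8), 7, 8)
    ours <- utrocular:::abs_tstat(xa, xb)
    theirs <- vapply(1:8, function(j) abs(oracle_two_sample_t(xa[, j], xb[, j])), 0)
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("degenerate voxels rank by the stated conventions", {
  # zero variance + zero difference -> |T| = 0, ranked last;
  # zero variance + nonzero difference -> Inf, ranked first
  x <- cbind(rep(1, 8), c(rnorm(4), rnorm(4)), rep(c(0, 1), each = 4))
  meta <- data.frame(condition = rep(c("L_low", "R_low"), each = 4),
                     run = rep(1:4, 2), stringsAsFactors = FALSE)
  smp <- pattern_samples(x, meta)
  sel <- tstat_rank_voxels(smp, "L_low", "R_low", cutoff = 3)
  expect_equal(sel[1], 3L)
  expect_equal(sel[3], 1L)
  # a 10-SD separated voxel beats a pure-noise voxel essentially always
  wins <- vapply(1:50, function(s) {
    set.seed(s + 300)
    xx <- cbind(rnorm(8), c(rnorm(4, 0, 1), rnorm(4, 10, 1)))
    smp2 <- pattern_samples(xx, meta)
    tstat_rank_voxels(smp2, "L_low", "R_low", 1)[1] == 2L
  }, TRUE)
  expect_true(all(wins))
})

test_that("responsiveness selection matches a mean-and-sort oracle", {
  x <- matrix(c(0, 0, 10, 0,
                1, 2, 0, 1,
                3, 3, 3, 3), nrow = 4)
  meta <- data.frame(condition = rep(c("L_low", "R_low"), 2), run = c(1, 1, 2, 2))
  smp <- pattern_samples(x, meta)
  expect_equal(select_responsive_voxels(smp, 3), oracle_rank_by_mean(x, 3))
  expect_equal(select_responsive_voxels(smp, 1), 3L)
  # cutoff beyond the voxel count returns everything
  expect_length(select_responsive_voxels(smp, 99), 3)
})

test_that("templates are per-condition means over training samples", {
  x <- rbind(c(1, 3), c(3, 5), c(0, 10), c(2, 8))
  meta <- data.frame(condition = c("L_low", "L_low", "R_low", "R_low"),
                     run = c(1, 2, 1, 2))
  smp <- pattern_samples(x, meta)
  tm <- build_templates(smp, c("L_low", "R_low"), 1:2)
  expect_equal(unname(tm["L_low", ]), c(2, 4))
  expect_equal(unname(tm["R_low", ]), c(1, 9))
  # permutation of training order leaves templates unchanged
  smp2 <- pattern_samples(x[c(3, 1, 4, 2), ], meta[c(3, 1, 4, 2), ])
  expect_equal(build_templates(smp2, c("L_low", "R_low"), 1:2), tm)
  # single sample per condition: template equals the sample
  one <- pattern_samples(x[1:2, ], meta[c(1, 3), ])
  tm1 <- build_templates(one, c("L_low", "R_low"), 1:2)
  expect_equal(unname(tm1["L_low", ]), c(1, 3))
})

test_that("correlation classification is affine-invariant and matches Pearson", {
  tm <- rbind(L_low = c(1, 0, 1), R_low = c(0, 1, 0))
  expect_equal(classify_correlation(c(1, 0, 1), tm)$label, "L_low")
  expect_equal(classify_correlation(2 * c(1, 0, 1) + 5, tm)$label, "L_low")
  res <- classify_correlation(c(1, 0, 0.5), tm)
  r_oracle <- oracle_classify_correlation(c(1, 0, 0.5),
                                          list(L_low = c(1, 0, 1),
                                               R_low = c(0, 1, 0)))
  expect_equal(res$label, r_oracle)
  # zero-variance test sample: undefined correlations, tie-broken + flagged
  flat <- classify_correlation(c(1, 1, 1), tm)
  expect_true(flat$tied)
  expect_equal(flat$label, "L_low")
  # randomized agreement with the brute-force decision
  set.seed(40)
  for (i in 1:50) {
    tmpl <- rbind(L_low = rnorm(6), R_low = rnorm(6))
    test <- rnorm(6)
    expect_equal(classify_correlation(test, tmpl)$label,
                 oracle_classify_correlation(test, list(L_low = tmpl[1, ],
                                                        R_low = tmpl[2, ])))
  }
})

test_that("univariate classification picks the nearer scalar template", {
  tm <- rbind(L_low = c(0, 0), R_low = c(1, 1))
  expect_equal(classify_univariate(c(0.4, 0.4), tm)$label, "L_low")
  expect_equal(classify_univariate(c(0.6, 0.6), tm)$label, "R_low")
  mid <- classify_univariate(c(0.5, 0.5), tm)
  expect_true(mid$tied)
  expect_equal(mid$label, "L_low")
  expect_equal(classify_univariate(c(0, 0), tm)$label, "L_low")
})

test_that("leave-one-run-out structure: 12 folds, 2 test samples per fold", {
  smp <- make_toy_samples(12, 30, signal_voxels = 1:5, delta = 4, seed = 2)
  res <- loro_cv(smp, decoding_config(c("L_low", "R_low"), n_voxels_cutoff = 10))
  expect_length(res$fold_accuracies, 12)
  expect_equal(res$n_samples, 24)
  expect_true(all(vapply(res$selected_voxels_per_fold, length, 0L) == 10))
  expect_gte(res$accuracy, 0.9)  # 4-SD separation on 5 voxels is easy
})

test_that("decoding a noise-free self-template dataset is perfect", {
  a <- c(1, 0, 1, 0, 2)
  b <- c(0, 1, 0, 1, 0)
  x <- rbind(a, b)[rep(1:2, 6), ]
  meta <- data.frame(condition = rep(c("L_low", "R_low"), 6),
                     run = rep(1:6, each = 2))
  smp <- pattern_samples(x, meta)
  res <- loro_cv(smp, decoding_config(c("L_low", "R_low"), n_voxels_cutoff = 5))
  expect_equal(res$accuracy, 1.0)
})

test_that("classifier decisions are invariant to affine maps of the test sample", {
  set.seed(44)
  for (i in 1:30) {
    tmpl <- rbind(L_low = rnorm(8), R_low = rnorm(8))
    test <- rnorm(8)
    a <- runif(1, 0.2, 4); b <- rnorm(1, 0, 10)
    expect_equal(classify_correlation(a * test + b, tmpl)$label,
                 classify_correlation(test, tmpl)$label)
  }
})

test_that("decoding is invariant to a global positive affine rescaling", {
  smp <- make_toy_samples(8, 40, signal_voxels = 1:6, delta = 1.5, seed = 3)
  scaled <- smp
  scaled$x <- 2.5 * smp$x - 4
  for (cls in c("pattern_correlation", "univariate_difference")) {
    expect_equal(
      loro_cv(scaled, decoding_config(c("L_low", "R_low"), 20, cls))$fold_accuracies,
      loro_cv(smp, decoding_config(c("L_low", "R_low"), 20, cls))$fold_accuracies)
  }
})

test_that("adding a common constant to every voxel changes neither classifier", {
  smp <- make_toy_samples(8, 40, signal_voxels = 1:6, delta = 1.5, seed = 5)
  shifted <- smp
  shifted$x <- smp$x + 7.5
  for (cls in c("pattern_correlation", "univariate_difference")) {
    expect_equal(
      loro_cv(shifted, decoding_config(c("L_low", "R_low"), 20, cls))$fold_accuracies,
      loro_cv(smp, decoding_config(c("L_low", "R_low"), 20, cls))$fold_accuracies)
  }
})

test_that("training-only selection stays at chance on pure noise", {
  # the circularity check: 100-voxel selection inside each fold must not
  # inflate held-out accuracy above chance
  accs <- vapply(1:200, function(s) {
    loro_cv(make_null_samples(12, 144, seed = s),
            decoding_config(c("L_low", "R_low"), 100))$accuracy
  }, 0)
  # 99% Monte-Carlo interval for the mean of 200 runs of 24 Bernoulli(1/2)
  se <- sqrt(0.25 / (200 * 24))
  expect_lt(abs(mean(accs) - 0.5), 2.576 * se + 0.01)
})

test_that("accuracy grows with the monocular gain of the generator", {
  mean_acc <- function(es, seeds = 1:12) {
    mean(vapply(seeds, function(s) {
      sheet <- cortical_sheet(size_mm = 9.6, mm_per_px = 0.1, seed = s)
      m <- response_model(eye_selectivity = es)
      ds <- simulate_experiment(sheet = sheet, model = m, seed = s + 700)
      loro_cv(preprocess_dataset(ds),
              decoding_config(c("L_low", "R_low"), 36))$accuracy
    }, 0))
  }
  a0 <- mean_acc(0); a4 <- mean_acc(0.4); a8 <- mean_acc(0.8)
  expect_lte(a0, a4 + 0.05)
  expect_lte(a4, a8 + 0.05)
  expect_gt(a8, a0 + 0.1)
})
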