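test_that("t_pvalue matches numerical integration of the t density", {
  expect_equal(t_pvalue(0, 5), 1)
  for (df in c(1, 2, 3, 7, 15, 30)) {
    for (t in c(0.3, 1.1, 2.04, 2.365, 3.9)) {
      expect_equal(t_pvalue(t, df), oracle_t_pvalue(t, df), tolerance = 1e-8)
      expect_equal(t_pvalue(-t, df), t_pvalue(t, df))
    }
  }
  # strictly decreasing in |t|
  ts <- seq(0, 6, by = 0.25)
  expect_true(all(diff(t_pvalue(ts, 7)) < 0))
  expect_equal(round(t_pvalue(2.365, 7), 3), 0.050)
  expect_error(t_pvalue(1, 0.5), "df")
})

test_that("bonferroni multiplies and clips", {
  expect_equal(bonferroni(0.004, 3), 0.012)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.01, 0.2), 1), c(0.01, 0.2))
  expect_error(bonferroni(0.05, 0), "family_size")
})

test_that("one-sample t follows the textbook formula", {
  res <- one_sample_t(c(52, 54, 56, 58), 50)
  expect_equal(res$statistic, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  # against stats::t.test as an independent oracle
  set.seed(60)
  for (i in 1:20) {
    v <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1))
    ours <- one_sample_t(v, 0.2)
    ref <- t.test(v, mu = 0.2)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(one_sample_t(c(1, 2, 3), 2)$statistic, 0)
  expect_equal(one_sample_t(c(1, 2, 3), 2)$p_two_tailed, 1)
  expect_error(one_sample_t(rep(5, 4), 5), "zero standard deviation")
})

test_that("paired t is antisymmetric and matches hand computation", {
  a <- c(2, 3, 4, 6); b <- c(1, 2, 3, 3)  # differences 1,1,1,3
  res <- paired_t(a, b)  # differences 1,1,1,3: mean 1.5, sd 1, t = 3
  expect_equal(res$statistic, 3, tolerance = 1e-12)
  expect_equal(res$df, 3)
  rev <- paired_t(b, a)
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p_two_tailed, res$p_two_tailed)
})

test_that("pearson_test matches cor.test and is symmetric", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    ours <- pearson_test(x, y)
    ref <- cor.test(x, y)
    expect_equal(unname(ours$estimate), unname(ref$estimate), tolerance = 1e-10)
    expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-10)
    swapped <- pearson_test(y, x)
    expect_identical(swapped$statistic, ours$statistic)
  }
  # degenerate and error paths
  expect_lt(pearson_test(1:5, (1:5) * 2)$p_two_tailed, 1e-20)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
  x <- c(-1, 0, 1, 2)
  yo <- unname(residuals(lm(c(1, -1, 1, -1) ~ x)))  # exactly uncorrelated with x
  expect_equal(pearson_test(x, yo)$p_two_tailed, 1, tolerance = 1e-8)
})

test_that("permutation p-values hit the floor when observed beats every null", {
  smp <- make_toy_samples(6, 20, signal_voxels = 1:10, delta = 8, seed = 7)
  pt <- permutation_test(smp, decoding_config(c("L_low", "R_low"), 10),
                         n_permutations = 99, seed = 1)
  expect_equal(pt$observed_accuracy, 1)
  expect_equal(pt$p_value, 1 / 100)
  expect_equal(pt$corrected_p, 3 / 100)
  expect_length(pt$null_accuracies, 99)
})

test_that("permutation test is bit-reproducible under a fixed seed", {
  smp <- make_toy_samples(6, 20, signal_voxels = 1:4, delta = 1, seed = 8)
  a <- permutation_test(smp, decoding_config(c("L_low", "R_low"), 10), 99, seed = 5)
  b <- permutation_test(smp, decoding_config(c("L_low", "R_low"), 10), 99, seed = 5)
  expect_identical(a$null_accuracies, b$null_accuracies)
  expect_identical(a$p_value, b$p_value)
  expect_error(permutation_test(smp, n_permutations = 10), "99")
})

test_that("permutation p-values are super-uniform on null data", {
  ps <- vapply(1:120, function(s) {
    permutation_test(make_null_samples(6, 40, seed = s),
                     decoding_config(c("L_low", "R_low"), 20),
                     n_permutations = 99, seed = s + 1e4)$p_value
  }, 0)
  for (alpha in c(0.05, 0.1, 0.25)) {
    emp <- mean(ps <= alpha)
    margin <- 2.576 * sqrt(alpha * (1 - alpha) / 120)
    expect_lte(emp, alpha + margin)
  }
})
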