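# Inference: permutation test for decoding accuracy, Bonferroni correction,
# and the analytic t / correlation tests.

#' Two-tailed p-value of a Student-t statistic
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `2 * P(T >= |t|)` under Student's t with `df` degrees of freedom.
#' @export
t_pvalue <- function(t, df) {
  if (!is.numeric(df) || any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and clips at 1.
#'
#' @param p Numeric vector of p-values.
#' @param family_size Number of tests in the family (>= 1).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, family_size) {
  if (family_size < 1) stop("family_size must be >= 1")
  pmin(1, p * family_size)
}

new_test_result <- function(method, statistic, df, p, estimate = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_two_tailed = p, estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  est <- if (!is.null(x$estimate)) sprintf("%s = %.3f, ",
                                           names(x$estimate), x$estimate) else ""
  cat(sprintf("%s: %st(%g) = %.3f, p = %.4g\n", x$method, est,
              x$df, x$statistic, x$p_two_tailed))
  invisible(x)
}

#' One-sample t test
#'
#' `t = (mean(values) - mu0) / (sd(values) / sqrt(n))` with `df = n - 1`,
#' two-tailed. Used for testing group decoding accuracies or behavioral
#' performance against chance.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param mu0 Null-hypothesis mean (e.g. 0.5 for chance accuracy).
#' @return A `"test_result"`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: t statistic undefined")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  new_test_result("one-sample t", t, n - 1L, t_pvalue(t, n - 1L),
                  estimate = c(mean = mean(values)))
}

#' Paired t test
#'
#' One-sample t test on the element-wise differences `a - b` against 0.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return A `"test_result"`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  res <- one_sample_t(a - b, 0)
  res$method <- "paired t"
  names(res$estimate) <- "mean difference"
  res
}

#' Pearson correlation test
#'
#' Computes the Pearson coefficient `r` and tests it against zero with
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return A `"test_result"` with `estimate = c(r = ...)`.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- t_pvalue(t, n - 2L)
  }
  res <- new_test_result("Pearson correlation", t, n - 2L, p,
                         estimate = c(r = r))
  res
}

#' Permutation test for above-chance decoding accuracy
#'
#' Builds the null distribution of leave-one-run-out decoding accuracy by
#' permuting the two problem condition labels within each run independently
#' (with one sample per condition per run this is a fair coin flip of the
#' two labels in each run), re-running the full pipeline — voxel selection,
#' templates, cross-validation — for every permutation. The p-value uses the
#' add-one estimator `p = (1 + #{null >= observed}) / (1 + n_permutations)`,
#' which can never be zero; ties with the observed accuracy count against
#' significance.
#'
#' @param samples A `"pattern_samples"` object.
#' @param config A [decoding_config()].
#' @param n_permutations Number of label permutations (>= 99; default 1000,
#'   which resolves p < 0.01 with margin).
#' @param seed Integer seed for the permutation draws.
#' @param family_size Bonferroni family size for the corrected p-value
#'   (default 3: the three visual areas typically tested together).
#' @return An object of class `"permutation_test"`: observed accuracy, null
#'   accuracies, `p_value`, `corrected_p`, `n_permutations`, `family_size`,
#'   `seed`.
#' @export
permutation_test <- function(samples, config = decoding_config(),
                             n_permutations = 1000, seed = 1,
                             family_size = 3) {
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  keep <- samples$meta$condition %in% config$problem
  x <- samples$x[keep, , drop = FALSE]
  cond <- samples$meta$condition[keep]
  run <- samples$meta$run[keep]
  runs <- unique(run)
  if (length(runs) < 2L) {
    stop("permutation space degenerate: need at least 2 runs")
  }
  observed <- mean(cv_core(x, cond, run, config$problem,
                           config$n_voxels_cutoff, config$classifier)$fold_accuracies)
  run_rows <- lapply(runs, function(r) which(run == r))
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      pcond <- cond
      for (rr in run_rows) pcond[rr] <- pcond[rr][sample.int(length(rr))]
      mean(cv_core(x, pcond, run, config$problem, config$n_voxels_cutoff,
                   config$classifier)$fold_accuracies)
    }, 0)
  })
  p <- (1 + sum(null_acc >= observed)) / (1 + n_permutations)
  structure(list(
    observed_accuracy = observed, null_accuracies = null_acc,
    p_value = p, corrected_p = bonferroni(p, family_size),
    n_permutations = as.integer(n_permutations),
    family_size = as.integer(family_size), seed = seed, config = config
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s vs %s, %s):\n", x$config$problem[1],
              x$config$problem[2], x$config$classifier))
  cat(sprintf("  observed accuracy %.3f; null mean %.3f (%d permutations)\n",
              x$observed_accuracy, mean(x$null_accuracies), x$n_permutations))
  cat(sprintf("  p = %.4g; Bonferroni-corrected (family %d) p = %.4g\n",
              x$p_value, x$family_size, x$corrected_p))
  invisible(x)
}
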