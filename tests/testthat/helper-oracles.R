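# Independent brute-force oracles, deliberately written from first
# principles (loops, direct formulas, numerical integration) so they share
# no code path with the package implementation.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

oracle_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# two-tailed t p-value by numerical integration of the t density
oracle_t_pvalue <- function(t, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

# d-prime / criterion from raw counts with the log-linear correction
oracle_sdt <- function(n_hit, n_sig, n_fa, n_noise) {
  h <- (n_hit + 0.5) / (n_sig + 1)
  f <- (n_fa + 0.5) / (n_noise + 1)
  list(dprime = qnorm(h) - qnorm(f), criterion = -(qnorm(h) + qnorm(f)) / 2)
}

# nearest-template-by-correlation decision, straight from the definition
oracle_classify_correlation <- function(test, template_list) {
  rs <- vapply(template_list, function(tm) oracle_pearson(test, tm), 0)
  names(template_list)[which.max(rs)]
}

# mean response ranking for responsiveness selection
oracle_rank_by_mean <- function(x, cutoff) {
  m <- apply(x, 2, mean)
  head(order(m, decreasing = TRUE), cutoff)
}

# small helpers used across test files
make_toy_run <- function(data, labels, tr_s = 3.2, run_index = 1L) {
  structure(list(data = data, volume_labels = labels, tr_s = tr_s,
                 run_index = run_index, condition_order = unique(
                   labels[labels != "fixation"])),
            class = "run_data")
}

# samples with a known per-voxel signal: cond A mean +delta/2 on signal
# voxels, cond B mean -delta/2, iid N(0, sd) noise, one sample per
# condition per run
make_toy_samples <- function(n_runs, n_voxels, signal_voxels = integer(0),
                             delta = 0, sd = 1, conditions = c("A_", "B_"),
                             seed = 1) {
  # conditions must parse as eye_sf tokens for package containers; use
  # L_low / R_low as the canonical binary problem
  set.seed(seed)
  conds <- c("L_low", "R_low")
  x <- matrix(rnorm(2 * n_runs * n_voxels, sd = sd), 2 * n_runs, n_voxels)
  mu <- numeric(n_voxels)
  # alternate signs so the between-condition pattern has cross-voxel
  # variance (a uniform shift is invisible to a correlation classifier)
  mu[signal_voxels] <- delta / 2 * rep_len(c(1, -1), length(signal_voxels))
  idx_a <- seq(1, 2 * n_runs, by = 2)
  x[idx_a, ] <- sweep(x[idx_a, , drop = FALSE], 2, mu, `+`)
  x[-idx_a, ] <- sweep(x[-idx_a, , drop = FALSE], 2, mu, `-`)
  meta <- data.frame(
    condition = rep(conds, n_runs), eye = NA, sf = "low",
    run = rep(seq_len(n_runs), each = 2),
    block = rep(1:2, n_runs), stringsAsFactors = FALSE)
  info <- utrocular:::parse_condition(meta$condition)
  meta$eye <- info$eye
  pattern_samples(x, meta)
}

# a pure-noise dataset generator used by null-calibration suites
make_null_samples <- function(n_runs = 12, n_voxels = 144, seed = 1) {
  make_toy_samples(n_runs, n_voxels, signal_voxels = integer(0), delta = 0,
                   seed = seed)
}
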