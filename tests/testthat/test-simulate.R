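toy_responses <- function(nv = 5) {
  r <- lapply(1:4, function(i) seq_len(nv) * i / 10)
  names(r) <- c("L_low", "L_high", "R_low", "R_high")
  r
}

test_that("default design yields 4 blocks of 6 labelled volumes per run", {
  run <- simulate_run(experiment_design(), toy_responses(), seed = 1)
  tab <- table(run$volume_labels)
  expect_equal(sort(names(tab)),
               sort(c("fixation", "L_low", "L_high", "R_low", "R_high")))
  expect_true(all(tab[names(tab) != "fixation"] == 6))
  blocks <- rle(run$volume_labels)
  expect_equal(sum(blocks$values != "fixation"), 4)
})

test_that("noise-free boxcar runs carry the condition response exactly", {
  resp <- toy_responses()
  m <- response_model(noise_sd = 0, hrf = "boxcar")
  run <- simulate_run(experiment_design(), resp, m, seed = 1)
  for (cond in names(resp)) {
    vols <- which(run$volume_labels == cond)
    for (v in vols) expect_equal(run$data[, v], resp[[cond]])
  }
  expect_true(all(run$data[, run$volume_labels == "fixation"] == 0))
})

test_that("order seed fixes labels while noise seed varies the data", {
  resp <- toy_responses()
  m <- response_model(noise_sd = 0.5)
  a <- simulate_run(experiment_design(), resp, m, seed = 1, order_seed = 99)
  b <- simulate_run(experiment_design(), resp, m, seed = 2, order_seed = 99)
  expect_identical(a$volume_labels, b$volume_labels)
  expect_false(identical(a$data, b$data))
  expect_identical(a$data,
                   simulate_run(experiment_design(), resp, m, seed = 1,
                                order_seed = 99)$data)
})

test_that("AR(1) noise keeps its stationary scale and autocorrelation", {
  resp <- lapply(toy_responses(200), function(r) r * 0)
  m <- response_model(noise_sd = 2, ar1_phi = 0.6, hrf = "boxcar")
  run <- simulate_run(experiment_design(), resp, m, seed = 4)
  x <- as.vector(run$data)
  expect_equal(sd(x), 2, tolerance = 0.05)
  lag1 <- cor(as.vector(run$data[, -1]), as.vector(run$data[, -ncol(run$data)]))
  expect_equal(lag1, 0.6, tolerance = 0.05)
})

test_that("condition list mismatches are rejected", {
  bad <- toy_responses()[1:3]
  expect_error(simulate_run(experiment_design(), bad, seed = 1),
               "named list")
})

test_that("a full experiment has 12 runs, 48 blocks, and is seed-reproducible", {
  sheet <- cortical_sheet(size_mm = 6.4, mm_per_px = 0.1, seed = 1)
  ds <- simulate_experiment(sheet = sheet, seed = 5)
  expect_length(ds$runs, 12)
  n_blocks <- sum(vapply(ds$runs, function(r) {
    sum(rle(r$volume_labels)$values != "fixation")
  }, 0L))
  expect_equal(n_blocks, 48)
  ds2 <- simulate_experiment(sheet = sheet, seed = 5)
  expect_identical(lapply(ds$runs, `[[`, "data"), lapply(ds2$runs, `[[`, "data"))
})

test_that("null models build datasets with no eye information", {
  sheet <- cortical_sheet(size_mm = 6.4, mm_per_px = 0.1, seed = 2)
  m <- response_model(eye_selectivity = 0, left_eye_offset_delta = 0)
  ds <- simulate_experiment(sheet = sheet, model = m, seed = 6)
  expect_equal(ds$ground_truth$responses$L_low, ds$ground_truth$responses$R_low)
  expect_equal(ds$ground_truth$responses$L_high, ds$ground_truth$responses$R_high)
})

test_that("the canonical HRF peaks near 6 s with a late undershoot", {
  t <- seq(0, 30, by = 0.1)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-4)  # grid does not hit the exact peak
  expect_equal(t[which.max(h)], 5.2, tolerance = 1)
  expect_lt(min(h[t > 10 & t < 25]), 0)
})
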