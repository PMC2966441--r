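hand_session <- function() {
  # 10 low-sf trials, 7 correct; 4 high-sf trials, all correct
  trials <- data.frame(
    stimulus_eye = c(rep("L", 5), rep("R", 5), "L", "L", "R", "R"),
    sf = c(rep("low", 10), rep("high", 4)),
    response_eye = c("L", "L", "L", "L", "R",  # 4 of 5 L-trials correct
                     "R", "R", "R", "L", "L",  # 3 of 5 R-trials correct
                     "L", "L", "R", "R"),
    stringsAsFactors = FALSE)
  behavioral_session(trials, dominant_eye = "L")
}

test_that("accuracy_by_sf counts proportions correct per spatial frequency", {
  acc <- accuracy_by_sf(hand_session())
  expect_equal(acc[["low"]], 0.7)
  expect_equal(acc[["high"]], 1.0)
  all_right <- hand_session()
  all_right$trials$response_eye <- all_right$trials$stimulus_eye
  expect_equal(unname(accuracy_by_sf(all_right)), c(1, 1))
  one_level <- hand_session()
  one_level$trials <- one_level$trials[one_level$trials$sf == "low", ]
  expect_warning(acc1 <- accuracy_by_sf(one_level), "missing")
  expect_named(acc1, "low")
})

test_that("sdt_analysis matches the count-based oracle and conventions", {
  s <- hand_session()
  # low sf: signal = L-stim (5, 4 'L' responses), noise = R-stim (5, 2 'L')
  res <- sdt_analysis(s, "low")
  orc <- oracle_sdt(4, 5, 2, 5)
  expect_equal(res$dprime, orc$dprime, tolerance = 1e-12)
  expect_equal(res$criterion, orc$criterion, tolerance = 1e-12)
  expect_false(res$correction_mattered)
  # equal hit and false-alarm rates give zero sensitivity
  flat <- behavioral_session(data.frame(
    stimulus_eye = rep(c("L", "R"), each = 4), sf = "low",
    response_eye = rep(c("L", "R", "L", "R"), 2),
    stringsAsFactors = FALSE), dominant_eye = "L")
  expect_equal(sdt_analysis(flat, "low")$dprime, 0)
  # perfect hit rate triggers the correction flag but stays finite
  perfect <- behavioral_session(data.frame(
    stimulus_eye = rep(c("L", "R"), each = 10), sf = "high",
    response_eye = c(rep("L", 10), rep("R", 8), "L", "L"),
    stringsAsFactors = FALSE), dominant_eye = "L")
  res_p <- sdt_analysis(perfect, "high")
  expect_true(res_p$correction_mattered)
  expect_true(is.finite(res_p$dprime))
})

test_that("sdt_analysis is invariant to trial order and flips with relabeling", {
  sess <- simulate_behavior(behavioral_design(n_trials = 200), seed = 5)
  res <- sdt_analysis(sess, "high")
  shuffled <- sess
  shuffled$trials <- sess$trials[sample(nrow(sess$trials)), ]
  expect_equal(sdt_analysis(shuffled, "high")$dprime, res$dprime)
  # relabeling the dominant eye swaps hit <-> 1 - fa exactly (the corrected
  # rates obey the complement identity), so d' is invariant and the
  # criterion flips sign
  flipped <- sess
  flipped$dominant_eye <- "R"
  expect_equal(sdt_analysis(flipped, "high")$dprime, res$dprime)
  expect_equal(sdt_analysis(flipped, "high")$criterion, -res$criterion)
  # swapping the stimulus classes (responses kept) is what flips d'
  swapped <- sess
  swapped$trials$stimulus_eye <- ifelse(sess$trials$stimulus_eye == "L", "R", "L")
  expect_equal(sdt_analysis(swapped, "high")$dprime, -res$dprime)
})

test_that("generative d' and criterion are recovered from simulated sessions", {
  des <- behavioral_design(dprime = c(low = 1, high = 0),
                           criterion = c(low = 0, high = 0.5))
  sessions <- lapply(1:100, function(s) simulate_behavior(des, seed = s))
  rec <- recover_generative_sdt(sessions)
  expect_lt(abs(rec$dprime_mean[rec$sf == "low"] - 1), 0.05)
  expect_lt(abs(rec$dprime_mean[rec$sf == "high"]), 0.05)
  expect_lt(abs(rec$criterion_mean[rec$sf == "high"] - 0.5), 0.05)
  expect_lt(abs(rec$criterion_mean[rec$sf == "low"]), 0.05)
  # unbiased observer accuracy approaches Phi(d'/2)
  expect_equal(rec$accuracy_mean[rec$sf == "low"], pnorm(0.5), tolerance = 0.02)
})

test_that("behavioral TSV round-trips", {
  sess <- simulate_behavior(behavioral_design(n_trials = 48), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_behavioral_tsv(sess, path)
  back <- read_behavioral_tsv(path, dominant_eye = "L", subject = "sim")
  expect_equal(back$trials$stimulus_eye, sess$trials$stimulus_eye)
  expect_equal(back$trials$response_eye, sess$trials$response_eye)
  expect_equal(accuracy_by_sf(back), accuracy_by_sf(sess))
})
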