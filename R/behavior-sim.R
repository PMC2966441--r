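# Simulated utrocular-discrimination sessions.

# Constraint check used both by the sampler and by tests:
#  (a) no identical condition on adjacent trials, anywhere;
#  (b) within each consecutive series of `series_length` trials, no identical
#      spatial frequency on adjacent trials (series boundaries reset).
sequence_constraints_ok <- function(condition, sf, series_length) {
  n <- length(condition)
  if (n < 2L) return(TRUE)
  if (any(condition[-1L] == condition[-n])) return(FALSE)
  pos <- ((seq_len(n) - 1L) %% series_length) + 1L  # position within series
  adj <- which(pos[-1L] != 1L)  # pairs (i, i+1) inside one series
  !any(sf[adj + 1L] == sf[adj])
}

# Sequential constrained sampling from a balanced deck, restarting on
# dead-ends. Candidates are drawn with probability proportional to their
# remaining count, which keeps the deck exactly balanced at completion.
generate_trial_sequence <- function(n_trials, conditions, series_length,
                                    max_restarts) {
  k <- length(conditions)
  if (n_trials %% k != 0L) {
    stop("n_trials must be divisible by the number of conditions (", k, ")")
  }
  info <- parse_condition(conditions)
  per <- n_trials %/% k
  for (attempt in seq_len(max_restarts)) {
    count <- rep(per, k)
    seqi <- integer(n_trials)
    ok <- TRUE
    for (t in seq_len(n_trials)) {
      cand <- which(count > 0L)
      if (t > 1L) {
        cand <- setdiff(cand, seqi[t - 1L])
        if ((t - 1L) %% series_length != 0L) {  # not at a series start
          cand <- cand[info$sf[cand] != info$sf[seqi[t - 1L]]]
        }
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      seqi[t] <- if (length(cand) == 1L) cand else {
        sample(cand, 1L, prob = count[cand])
      }
      count[seqi[t]] <- count[seqi[t]] - 1L
    }
    if (ok) return(seqi)
  }
  stop("failed to generate a constraint-satisfying trial sequence within ",
       max_restarts, " restarts; constraints may be infeasible for this design",
       call. = FALSE)
}

#' Simulate a behavioral utrocular-discrimination session
#'
#' Draws a constraint-satisfying trial sequence (balanced across the four
#' eye x spatial-frequency conditions) and generates responses from the
#' equal-variance Gaussian signal-detection model described in
#' [behavioral_design()]: evidence `N(+d'/2, 1)` when the dominant eye is
#' stimulated, `N(-d'/2, 1)` otherwise, response "dominant eye" when the
#' evidence exceeds the criterion for that trial's spatial frequency.
#'
#' @param design A [behavioral_design()].
#' @param seed Integer seed; fully determines the session.
#' @param subject Optional subject identifier stored on the session.
#' @return A `"behavioral_session"`: list with `trials` (data frame with
#'   columns `trial`, `stimulus_eye`, `sf`, `response_eye`), `dominant_eye`,
#'   `subject`.
#' @export
simulate_behavior <- function(design = behavioral_design(), seed = 1,
                              subject = "sim") {
  conditions <- c("L_low", "L_high", "R_low", "R_high")
  info <- parse_condition(conditions)
  with_seed(seed, {
    seqi <- generate_trial_sequence(design$n_trials, conditions,
                                    design$series_length, design$max_restarts)
    eye <- info$eye[seqi]
    sf <- info$sf[seqi]
    is_signal <- eye == design$dominant_eye
    dpr <- design$dprime[sf]
    crit <- design$criterion[sf]
    evidence <- stats::rnorm(design$n_trials,
                             mean = ifelse(is_signal, dpr / 2, -dpr / 2))
    say_dominant <- evidence > crit
    other <- if (design$dominant_eye == "L") "R" else "L"
    response <- ifelse(say_dominant, design$dominant_eye, other)
    behavioral_session(
      data.frame(trial = seq_len(design$n_trials), stimulus_eye = eye,
                 sf = sf, response_eye = response, stringsAsFactors = FALSE),
      dominant_eye = design$dominant_eye, subject = subject
    )
  })
}
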