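#' Block-design fMRI experiment description
#'
#' Describes the scanning protocol: a small number of stimulation conditions,
#' each shown once per run as a block of fixed duration, interleaved with
#' fixation blocks of the same duration. The defaults reproduce a 12-run
#' protocol with four conditions (left/right eye crossed with low/high
#' spatial frequency), 19.2 s blocks and fixation periods, and a repetition
#' time (TR) of 3.2 s, so that each block spans exactly 6 volumes.
#'
#' @param n_runs Number of runs (default 12).
#' @param conditions Character vector of condition labels `"<eye>_<sf>"` with
#'   eye in `{L, R}` and sf in `{low, high}`. Every condition occurs exactly
#'   once per run, in a pseudo-random order drawn per run.
#' @param block_duration_s Stimulation block duration in seconds (19.2).
#' @param fixation_duration_s Fixation duration in seconds (19.2). Runs start
#'   and end with a fixation block.
#' @param tr_s Volume repetition time in seconds (3.2). Must divide
#'   `block_duration_s` and `fixation_duration_s` exactly.
#' @return An object of class `"experiment_design"`.
#' @examples
#' d <- experiment_design()
#' d$volumes_per_block  # 6
#' @export
experiment_design <- function(n_runs = 12,
                              conditions = c("L_low", "L_high", "R_low", "R_high"),
                              block_duration_s = 19.2,
                              fixation_duration_s = 19.2,
                              tr_s = 3.2) {
  stopif_not_scalar_number(n_runs, "n_runs", min = 1)
  stopif_not_scalar_number(block_duration_s, "block_duration_s", min = 1e-9)
  stopif_not_scalar_number(fixation_duration_s, "fixation_duration_s", min = 0)
  stopif_not_scalar_number(tr_s, "tr_s", min = 1e-9)
  if (anyDuplicated(conditions)) stop("conditions must be distinct")
  parse_condition(conditions)  # validates tokens
  vpb <- block_duration_s / tr_s
  vpf <- fixation_duration_s / tr_s
  if (abs(vpb - round(vpb)) > 1e-9 || round(vpb) < 1) {
    stop("block_duration_s must be a positive integer multiple of tr_s")
  }
  if (abs(vpf - round(vpf)) > 1e-9) {
    stop("fixation_duration_s must be an integer multiple of tr_s")
  }
  structure(list(
    n_runs = as.integer(n_runs),
    conditions = conditions,
    block_duration_s = block_duration_s,
    fixation_duration_s = fixation_duration_s,
    tr_s = tr_s,
    volumes_per_block = as.integer(round(vpb)),
    volumes_per_fixation = as.integer(round(vpf))
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Block-design experiment\n")
  cat(sprintf("  %d runs x %d conditions (%s)\n", x$n_runs,
              length(x$conditions), paste(x$conditions, collapse = ", ")))
  cat(sprintf("  blocks %.1f s / fixation %.1f s at TR %.1f s (%d volumes/block)\n",
              x$block_duration_s, x$fixation_duration_s, x$tr_s,
              x$volumes_per_block))
  invisible(x)
}

#' Behavioral utrocular-discrimination session design
#'
#' Describes a two-alternative eye-of-origin judgement session: on each trial
#' a grating of low or high spatial frequency is shown to one eye and the
#' observer reports which eye saw it. Trial ordering obeys two constraints:
#' the same condition (eye x sf) never occurs on consecutive trials, and
#' within each consecutive series of 8 trials the same spatial frequency
#' never occurs on adjacent trials.
#'
#' Responses are generated from the equal-variance Gaussian signal-detection
#' model in which "dominant eye stimulated" is the signal class: on a trial
#' with spatial frequency s the internal evidence is
#' `N(+d'_s/2, 1)` for dominant-eye and `N(-d'_s/2, 1)` for
#' non-dominant-eye stimulation, and the observer reports "dominant" when the
#' evidence exceeds the criterion `c_s`. Positive criterion means a
#' conservative bias against reporting the dominant eye.
#'
#' Default sensitivities and criteria are the group estimates from the
#' utrocular-discrimination literature this package models: d' of -0.13 (low
#' sf) and 0.96 (high sf), criterion 0.07 and 0.16, dominant eye left.
#'
#' @param n_trials Number of trials (default 624; must be divisible by the
#'   number of conditions for the balanced deck, and by 8 for the series
#'   constraint to tile the session).
#' @param stimulus_duration_ms Stimulus duration in ms (350; metadata only).
#' @param dprime Named numeric `c(low=, high=)`: generative sensitivity per
#'   spatial frequency, in z-units.
#' @param criterion Named numeric `c(low=, high=)`: generative response
#'   criterion per spatial frequency, in z-units.
#' @param dominant_eye `"L"` or `"R"`.
#' @param series_length Length of the non-overlapping trial series within
#'   which spatial frequency may not repeat on adjacent trials (8).
#' @param max_restarts Restart budget for the constrained sequence sampler.
#' @return An object of class `"behavioral_design"`.
#' @export
behavioral_design <- function(n_trials = 624,
                              stimulus_duration_ms = 350,
                              dprime = c(low = -0.13, high = 0.96),
                              criterion = c(low = 0.07, high = 0.16),
                              dominant_eye = "L",
                              series_length = 8,
                              max_restarts = 1e5) {
  stopif_not_scalar_number(n_trials, "n_trials", min = 2)
  if (!all(c("low", "high") %in% names(dprime)) ||
      !all(c("low", "high") %in% names(criterion))) {
    stop("dprime and criterion must be named vectors with entries 'low' and 'high'")
  }
  if (!dominant_eye %in% c("L", "R")) stop("dominant_eye must be 'L' or 'R'")
  structure(list(
    n_trials = as.integer(n_trials),
    stimulus_duration_ms = stimulus_duration_ms,
    dprime = dprime[c("low", "high")],
    criterion = criterion[c("low", "high")],
    dominant_eye = dominant_eye,
    series_length = as.integer(series_length),
    max_restarts = as.integer(max_restarts)
  ), class = "behavioral_design")
}

#' @export
print.behavioral_design <- function(x, ...) {
  cat(sprintf("Utrocular discrimination session: %d trials, %d ms stimuli\n",
              x$n_trials, x$stimulus_duration_ms))
  cat(sprintf("  generative d' (low, high) = (%.2f, %.2f); criterion = (%.2f, %.2f)\n",
              x$dprime[["low"]], x$dprime[["high"]],
              x$criterion[["low"]], x$criterion[["high"]]))
  cat(sprintf("  dominant eye: %s\n", x$dominant_eye))
  invisible(x)
}
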