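# Behavioral analysis: accuracy and equal-variance signal detection theory.

#' Behavioral session container
#'
#' Trial-level records of a two-alternative eye-of-origin judgement task.
#'
#' @param trials Data frame with columns `stimulus_eye` (`"L"`/`"R"`),
#'   `sf` (`"low"`/`"high"`), `response_eye` (`"L"`/`"R"`); a `trial` column
#'   is added when absent.
#' @param dominant_eye The observer's sighting-dominant eye, `"L"` or `"R"`.
#' @param subject Subject identifier.
#' @return An object of class `"behavioral_session"`.
#' @export
behavioral_session <- function(trials, dominant_eye, subject = "s1") {
  req <- c("stimulus_eye", "sf", "response_eye")
  if (!all(req %in% names(trials))) {
    stop("trials must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("session has no trials")
  if (!all(trials$stimulus_eye %in% c("L", "R")) ||
      !all(trials$response_eye %in% c("L", "R")) ||
      !all(trials$sf %in% c("low", "high"))) {
    stop("invalid token in trials (eyes must be L/R, sf low/high)")
  }
  if (!dominant_eye %in% c("L", "R")) stop("dominant_eye must be 'L' or 'R'")
  if (is.null(trials$trial)) trials$trial <- seq_len(nrow(trials))
  structure(list(trials = trials, dominant_eye = dominant_eye,
                 subject = subject), class = "behavioral_session")
}

#' @export
print.behavioral_session <- function(x, ...) {
  cat(sprintf("Behavioral session '%s': %d trials, dominant eye %s\n",
              x$subject, nrow(x$trials), x$dominant_eye))
  acc <- accuracy_by_sf(x)
  cat(sprintf("  accuracy: low %.1f%%, high %.1f%%\n",
              100 * acc[["low"]], 100 * acc[["high"]]))
  invisible(x)
}

#' Proportion correct per spatial frequency
#'
#' @param session A [behavioral_session()].
#' @return Named numeric vector of proportions correct (response eye equals
#'   stimulated eye), one entry per spatial frequency present; a missing
#'   level is omitted with a warning.
#' @export
accuracy_by_sf <- function(session) {
  tr <- session$trials
  out <- vapply(c("low", "high"), function(s) {
    idx <- tr$sf == s
    if (!any(idx)) return(NA_real_)
    mean(tr$response_eye[idx] == tr$stimulus_eye[idx])
  }, 0)
  if (anyNA(out)) {
    warning("missing spatial-frequency level(s): ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Signal-detection analysis of dominant-eye detection
#'
#' Treats "dominant eye stimulated" as the signal class and "responded with
#' the dominant eye" as a yes. Hit and false-alarm rates are estimated with
#' the log-linear correction (0.5 added to each count, 1 to each
#' denominator), applied always so the estimator is continuous and finite;
#' `correction_mattered` flags sessions where a raw rate was 0 or 1.
#' Sensitivity and bias follow the equal-variance Gaussian model:
#' `d' = z(hit) - z(fa)` and `criterion = -(z(hit) + z(fa)) / 2`, with
#' positive criterion meaning a conservative bias against reporting the
#' dominant eye.
#'
#' @param session A [behavioral_session()].
#' @param sf `"low"` or `"high"`: which spatial frequency's trials to analyze.
#' @return An object of class `"sdt_result"`: list with `hit_rate`,
#'   `fa_rate`, `dprime`, `criterion`, trial counts and the correction flag.
#' @export
sdt_analysis <- function(session, sf) {
  if (!sf %in% c("low", "high")) stop("sf must be 'low' or 'high'")
  tr <- session$trials[session$trials$sf == sf, , drop = FALSE]
  signal <- tr$stimulus_eye == session$dominant_eye
  yes <- tr$response_eye == session$dominant_eye
  n_sig <- sum(signal); n_noise <- sum(!signal)
  if (n_sig == 0L || n_noise == 0L) {
    stop("need at least one dominant-eye and one non-dominant-eye trial at sf=", sf)
  }
  raw_hit <- sum(yes & signal) / n_sig
  raw_fa <- sum(yes & !signal) / n_noise
  hit <- (sum(yes & signal) + 0.5) / (n_sig + 1)
  fa <- (sum(yes & !signal) + 0.5) / (n_noise + 1)
  zh <- stats::qnorm(hit); zf <- stats::qnorm(fa)
  structure(list(
    sf = sf, n_signal = n_sig, n_noise = n_noise,
    hit_rate = hit, fa_rate = fa,
    dprime = zh - zf, criterion = -(zh + zf) / 2,
    correction_mattered = raw_hit %in% c(0, 1) || raw_fa %in% c(0, 1)
  ), class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("SDT (%s sf): d' = %.3f, criterion = %.3f (hit %.3f, fa %.3f; n = %d+%d)%s\n",
              x$sf, x$dprime, x$criterion, x$hit_rate, x$fa_rate,
              x$n_signal, x$n_noise,
              if (x$correction_mattered) " [extreme-rate correction]" else ""))
  invisible(x)
}

#' Recover generative signal-detection parameters from simulated sessions
#'
#' Applies [sdt_analysis()] to each session and averages the estimates per
#' spatial frequency — the parameter-recovery companion to
#' [simulate_behavior()].
#'
#' @param sessions List of [behavioral_session()] objects.
#' @return Data frame with one row per spatial frequency: mean and SD of the
#'   estimated d' and criterion across sessions, plus mean accuracy.
#' @export
recover_generative_sdt <- function(sessions) {
  rows <- lapply(c("low", "high"), function(s) {
    est <- lapply(sessions, sdt_analysis, sf = s)
    acc <- vapply(sessions, function(x) accuracy_by_sf(x)[[s]], 0)
    data.frame(
      sf = s, n_sessions = length(sessions),
      dprime_mean = mean(vapply(est, `[[`, 0, "dprime")),
      dprime_sd = stats::sd(vapply(est, `[[`, 0, "dprime")),
      criterion_mean = mean(vapply(est, `[[`, 0, "criterion")),
      criterion_sd = stats::sd(vapply(est, `[[`, 0, "criterion")),
      accuracy_mean = mean(acc),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read / write behavioral trial tables
#'
#' Plain TSV with columns `trial`, `stimulus_eye`, `sf`, `response_eye`.
#'
#' @param session A [behavioral_session()].
#' @param path File path.
#' @param dominant_eye,subject Session metadata to attach on read.
#' @return `write_behavioral_tsv` returns `path` invisibly;
#'   `read_behavioral_tsv` returns a [behavioral_session()].
#' @export
write_behavioral_tsv <- function(session, path) {
  utils::write.table(session$trials[, c("trial", "stimulus_eye", "sf", "response_eye")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavioral_tsv
#' @export
read_behavioral_tsv <- function(path, dominant_eye, subject = "s1") {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  behavioral_session(tr, dominant_eye = dominant_eye, subject = subject)
}
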