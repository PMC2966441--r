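# Block-design BOLD run simulation.

#' Canonical double-gamma hemodynamic response, sampled at arbitrary times
#'
#' Standard two-gamma impulse response (peak near 6 s, undershoot near 16 s,
#' undershoot ratio 1/6), rescaled to unit peak.
#'
#' @param t Times in seconds (>= 0).
#' @return Response values, unit peak.
#' @export
hrf_double_gamma <- function(t) {
  g <- function(u) stats::dgamma(u, shape = 6, rate = 1) -
    stats::dgamma(u, shape = 16, rate = 1) / 6
  peak <- g(stats::optimize(g, c(0, 10), maximum = TRUE, tol = 1e-10)$maximum)
  g(t) / peak
}

# One regressor per block: boxcar over the block's volumes, optionally
# convolved with the HRF sampled at TR resolution.
block_regressor <- function(n_vol, block_vols, tr_s, hrf) {
  box <- numeric(n_vol)
  box[block_vols] <- 1
  if (hrf == "boxcar") return(box)
  t <- seq(0, 32, by = tr_s)
  kern <- hrf_double_gamma(t)
  stats::convolve(box, rev(kern), type = "open")[seq_len(n_vol)]
}

# volume layout of one run: leading fixation, then for each block
# stimulation followed by fixation
run_layout <- function(design, order) {
  vpb <- design$volumes_per_block
  vpf <- design$volumes_per_fixation
  labels <- rep("fixation", vpf)
  onsets <- integer(length(order))
  for (i in seq_along(order)) {
    onsets[i] <- length(labels) + 1L
    labels <- c(labels, rep(order[i], vpb), rep("fixation", vpf))
  }
  list(labels = labels, onsets = onsets, n_vol = length(labels))
}

#' Simulate one block-design fMRI run
#'
#' Builds a voxels x volumes data matrix whose noise-free expectation is, for
#' each block, the condition's voxel response vector modulated by a
#' hemodynamic time course (canonical double-gamma, or an idealized unit
#' boxcar for exact tests), with expectation zero during fixation. AR(1)
#' Gaussian noise with stationary SD `model$noise_sd` is added per voxel,
#' independently across voxels.
#'
#' @param design An [experiment_design()].
#' @param responses Named list: one noise-free voxel response vector per
#'   condition in `design$conditions` (from [sample_voxels()]).
#' @param model A [response_model()] (supplies `noise_sd`, `ar1_phi`, `hrf`).
#' @param run_index Integer run identifier.
#' @param seed Seed for the noise realization.
#' @param order_seed Seed for the pseudo-random condition order; defaults to
#'   a value derived from `seed`. Fixing `order_seed` while varying `seed`
#'   reproduces the same label sequence with fresh noise.
#' @return An object of class `"run_data"`: list with `data`
#'   (voxels x volumes), `volume_labels`, `tr_s`, `run_index`,
#'   `condition_order`.
#' @export
simulate_run <- function(design, responses, model = response_model(),
                         run_index = 1L, seed = 1, order_seed = NULL) {
  if (!inherits(design, "experiment_design")) stop("design must be an experiment_design")
  if (!setequal(names(responses), design$conditions)) {
    stop("responses must be a named list with exactly the design's conditions")
  }
  nv <- length(responses[[1]])
  if (!all(vapply(responses, length, 0L) == nv)) {
    stop("all condition response vectors must have equal length")
  }
  if (is.null(order_seed)) order_seed <- derive_seed(seed, 77)
  order <- with_seed(order_seed, sample(design$conditions))
  lay <- run_layout(design, order)
  vpb <- design$volumes_per_block

  expect <- matrix(0, nv, lay$n_vol)
  for (i in seq_along(order)) {
    vols <- lay$onsets[i]:(lay$onsets[i] + vpb - 1L)
    reg <- block_regressor(lay$n_vol, vols, design$tr_s, model$hrf)
    expect <- expect + outer(as.numeric(responses[[order[i]]]), reg)
  }

  if (model$noise_sd > 0) {
    noise <- with_seed(seed, {
      e <- matrix(stats::rnorm(nv * lay$n_vol), nv, lay$n_vol)
      phi <- model$ar1_phi
      if (phi > 0) {
        scl <- sqrt(1 - phi^2)
        for (t in 2:lay$n_vol) e[, t] <- phi * e[, t - 1L] + scl * e[, t]
      }
      model$noise_sd * e
    })
    expect <- expect + noise
  }

  structure(list(data = expect, volume_labels = lay$labels,
                 tr_s = design$tr_s, run_index = as.integer(run_index),
                 condition_order = order),
            class = "run_data")
}

#' @export
print.run_data <- function(x, ...) {
  cat(sprintf("fMRI run %d: %d voxels x %d volumes (TR %.1f s)\n",
              x$run_index, nrow(x$data), ncol(x$data), x$tr_s))
  cat("  block order:", paste(x$condition_order, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a full multi-run experiment from a cortical sheet
#'
#' Runs the whole forward chain: evaluate the noise-free neural response of
#' the sheet to each condition, sample it into voxels, then simulate
#' `design$n_runs` block-design runs with independent noise and per-run
#' pseudo-random condition orders. The ground truth (sheet, model, noise-free
#' per-condition voxel responses) is stored alongside the runs so that
#' recovery tests can compare decoded quantities against it.
#'
#' @param design An [experiment_design()].
#' @param sheet A [cortical_sheet()].
#' @param model A [response_model()].
#' @param sampling A [voxel_sampling()].
#' @param seed Master seed; all per-run seeds are derived from it.
#' @return An object of class `"voxel_dataset"`: list with `runs` (list of
#'   [simulate_run()] results) and `ground_truth`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                sheet = cortical_sheet(),
                                model = response_model(),
                                sampling = voxel_sampling(),
                                seed = 1) {
  cond <- design$conditions
  info <- parse_condition(cond)
  responses <- lapply(seq_along(cond), function(i) {
    sample_voxels(neural_response(sheet, info$eye[i], info$sf[i], model), sampling)
  })
  names(responses) <- cond
  runs <- lapply(seq_len(design$n_runs), function(i) {
    simulate_run(design, responses, model, run_index = i,
                 seed = derive_seed(seed, 1000 + i),
                 order_seed = derive_seed(seed, 2000 + i))
  })
  structure(list(
    runs = runs,
    ground_truth = list(sheet = sheet, model = model, sampling = sampling,
                        design = design, responses = responses, seed = seed)
  ), class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d runs, %d voxels, %d volumes/run\n",
              length(x$runs), nrow(x$runs[[1]]$data), ncol(x$runs[[1]]$data)))
  invisible(x)
}
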