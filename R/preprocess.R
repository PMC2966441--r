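# Run-level preprocessing: z-normalization and block-averaged pattern samples.

#' Z-score normalize a run's time courses
#'
#' Normalizes each voxel's time course over the run's full duration
#' (stimulation and fixation volumes alike) to mean 0 and standard deviation
#' 1. The population SD convention (denominator n) is used so the transform
#' is exactly idempotent up to scale; correlation-based decoding is invariant
#' to the choice. Voxels with zero variance map to all-zero time courses.
#'
#' @param run A `"run_data"` object.
#' @return The run with `data` replaced by its normalized version.
#' @export
znormalize_run <- function(run) {
  x <- run$data
  if (ncol(x) < 2L) stop("need at least 2 volumes to normalize")
  m <- rowMeans(x)
  x <- x - m
  s <- sqrt(rowMeans(x^2))
  zero <- s == 0
  s[zero] <- 1
  x <- x / s
  x[zero, ] <- 0
  run$data <- x
  run
}

# maximal constant-label stimulation stretches
find_blocks <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "fixation"
  data.frame(condition = r$values[keep], start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

#' Extract one pattern sample per stimulation block
#'
#' Identifies stimulation blocks as maximal stretches of constant non-fixation
#' volume labels, shifts each block's assignment window forward by
#' `lag_volumes` volumes to account for hemodynamic lag (1 volume = one TR by
#' default), and averages the volumes in the shifted window into a single
#' voxel pattern ("sample") per block. Volumes shifted past the end of the
#' run are dropped from the average; a block whose entire window falls off
#' the end is an error.
#'
#' @param run A `"run_data"` object (typically z-normalized first).
#' @param lag_volumes Non-negative integer hemodynamic lag in volumes
#'   (default 1).
#' @return A `"pattern_samples"` object: list with `x` (samples x voxels
#'   matrix) and `meta` (data frame with `condition`, `eye`, `sf`, `run`,
#'   `block`).
#' @export
extract_samples <- function(run, lag_volumes = 1L) {
  if (lag_volumes < 0) stop("lag_volumes must be >= 0")
  lag_volumes <- as.integer(lag_volumes)
  blocks <- find_blocks(run$volume_labels)
  if (nrow(blocks) == 0L) stop("run contains no stimulation blocks")
  n_vol <- ncol(run$data)
  rows <- matrix(NA_real_, nrow(blocks), nrow(run$data))
  for (b in seq_len(nrow(blocks))) {
    vols <- (blocks$start[b]:blocks$end[b]) + lag_volumes
    vols <- vols[vols <= n_vol]
    if (length(vols) == 0L) {
      stop(sprintf("block %d ('%s') has no volumes left after lag %d",
                   b, blocks$condition[b], lag_volumes))
    }
    rows[b, ] <- rowMeans(run$data[, vols, drop = FALSE])
  }
  info <- parse_condition(blocks$condition)
  pattern_samples(rows, data.frame(
    condition = blocks$condition, eye = info$eye, sf = info$sf,
    run = run$run_index, block = seq_len(nrow(blocks)),
    stringsAsFactors = FALSE
  ))
}

#' Pattern-sample container
#'
#' @param x Numeric matrix, samples in rows, voxels in columns.
#' @param meta Data frame with one row per sample; must contain columns
#'   `condition` and `run`.
#' @return An object of class `"pattern_samples"`.
#' @export
pattern_samples <- function(x, meta) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(meta)) stop("x and meta must have matching rows")
  if (!all(c("condition", "run") %in% names(meta))) {
    stop("meta must contain columns 'condition' and 'run'")
  }
  structure(list(x = x, meta = meta), class = "pattern_samples")
}

#' @export
print.pattern_samples <- function(x, ...) {
  cat(sprintf("Pattern samples: %d samples x %d voxels, %d run(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$run))))
  print(table(x$meta$condition))
  invisible(x)
}

#' Combine samples from several runs
#'
#' @param ... `"pattern_samples"` objects with identical voxel counts.
#' @return One combined `"pattern_samples"`.
#' @export
bind_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "pattern_samples")) {
    parts <- parts[[1]]
  }
  pattern_samples(do.call(rbind, lapply(parts, `[[`, "x")),
                  do.call(rbind, lapply(parts, `[[`, "meta")))
}

#' Preprocess a whole simulated dataset into pattern samples
#'
#' Applies [znormalize_run()] and [extract_samples()] to every run of a
#' [simulate_experiment()] dataset and binds the result.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param lag_volumes Hemodynamic lag in volumes (see [extract_samples()]).
#' @return A `"pattern_samples"` object covering all runs.
#' @export
preprocess_dataset <- function(dataset, lag_volumes = 1L) {
  bind_samples(lapply(dataset$runs, function(r) {
    extract_samples(znormalize_run(r), lag_volumes)
  }))
}
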