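# File interchange: NIfTI volumes + ROI masks, BIDS-style events tables,
# pattern-sample matrices, ground-truth sidecars.

# events table (onset / duration / trial_type) from per-volume labels
events_from_labels <- function(labels, tr_s) {
  b <- find_blocks(labels)
  data.frame(onset = (b$start - 1) * tr_s,
             duration = (b$end - b$start + 1) * tr_s,
             trial_type = b$condition,
             stringsAsFactors = FALSE)
}

labels_from_events <- function(events, n_vol, tr_s) {
  labels <- rep("fixation", n_vol)
  for (i in seq_len(nrow(events))) {
    start <- round(events$onset[i] / tr_s) + 1L
    len <- round(events$duration[i] / tr_s)
    labels[start:(start + len - 1L)] <- events$trial_type[i]
  }
  labels
}

#' Write a simulated run as NIfTI + events TSV
#'
#' The voxel grid of the simulated 2D sheet becomes a single-slice 3D
#' volume; volumes are stacked along the 4th dimension. Condition timing is
#' written as a BIDS-style events table with columns `onset` (s), `duration`
#' (s), `trial_type`.
#'
#' @param run A `"run_data"` object.
#' @param dim_vox Voxel-grid dimensions `c(nx, ny)`; defaults to a single
#'   row when unknown (e.g. after ROI masking).
#' @param path_nii,path_events Output file paths (`.nii` and `.tsv`).
#' @param voxel_mm Voxel edge length recorded in the NIfTI header.
#' @return Invisibly, the NIfTI path.
#' @export
write_run_nifti <- function(run, path_nii, path_events,
                            dim_vox = NULL, voxel_mm = 1.5) {
  nv <- nrow(run$data)
  if (is.null(dim_vox)) dim_vox <- c(nv, 1L)
  if (prod(dim_vox) != nv) stop("dim_vox inconsistent with voxel count")
  arr <- array(run$data, dim = c(dim_vox[1], dim_vox[2], 1L, ncol(run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_mm, voxel_mm, voxel_mm, run$tr_s)
  RNifti::writeNifti(img, path_nii)
  utils::write.table(events_from_labels(run$volume_labels, run$tr_s),
                     path_events, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_nii)
}

#' Read a run from NIfTI + events TSV (+ optional ROI mask)
#'
#' @param path_nii 4D NIfTI file.
#' @param path_events Events TSV with `onset`, `duration`, `trial_type`.
#' @param path_mask Optional 3D NIfTI mask; nonzero voxels form the ROI.
#' @param tr_s Repetition time in seconds; read from the NIfTI header when
#'   omitted.
#' @param run_index Run identifier to attach.
#' @return A `"run_data"` object (voxels in column-major mask order).
#' @export
read_run_nifti <- function(path_nii, path_events, path_mask = NULL,
                           tr_s = NULL, run_index = 1L) {
  img <- RNifti::readNifti(path_nii)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI image")
  if (is.null(tr_s)) tr_s <- RNifti::pixdim(img)[4]
  mat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  if (!is.null(path_mask)) {
    mask <- as.numeric(RNifti::readNifti(path_mask)) != 0
    if (length(mask) != prod(d[1:3])) stop("mask does not match image grid")
    mat <- mat[mask, , drop = FALSE]
  }
  events <- utils::read.table(path_events, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  structure(list(data = mat,
                 volume_labels = labels_from_events(events, d[4], tr_s),
                 tr_s = tr_s, run_index = as.integer(run_index),
                 condition_order = events$trial_type),
            class = "run_data")
}

#' Write / read a pattern-sample matrix as CSV
#'
#' Rows are samples; label columns `condition`, `eye`, `sf`, `run`, `block`
#' precede the voxel columns `v1..vN`.
#'
#' @param samples A `"pattern_samples"` object.
#' @param path CSV file path.
#' @return `write_samples_csv` returns `path` invisibly; `read_samples_csv`
#'   returns a `"pattern_samples"`.
#' @export
write_samples_csv <- function(samples, path) {
  vox <- as.data.frame(samples$x)
  names(vox) <- paste0("v", seq_len(ncol(vox)))
  utils::write.csv(cbind(samples$meta, vox), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  voxcols <- grep("^v[0-9]+$", names(df))
  pattern_samples(as.matrix(df[, voxcols, drop = FALSE]),
                  df[, setdiff(seq_along(df), voxcols), drop = FALSE])
}

#' Write a simulated dataset bundle to disk
#'
#' One NIfTI + events TSV per run, an all-ones ROI mask, and a JSON
#' ground-truth sidecar recording every generator parameter and seed.
#'
#' @param dataset A `"voxel_dataset"` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, a character vector of written file paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- dataset$ground_truth
  dim_vox <- attr(gt$responses[[1]], "dim_vox")
  if (is.null(dim_vox)) dim_vox <- c(length(gt$responses[[1]]), 1L)
  paths <- character(0)
  for (run in dataset$runs) {
    nii <- file.path(dir, sprintf("%s_run-%02d_bold.nii", prefix, run$run_index))
    ev <- file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, run$run_index))
    write_run_nifti(run, nii, ev, dim_vox = dim_vox,
                    voxel_mm = gt$sampling$voxel_mm)
    paths <- c(paths, nii, ev)
  }
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii"))
  mask <- RNifti::asNifti(array(1, dim = c(dim_vox[1], dim_vox[2], 1L)))
  RNifti::writeNifti(mask, mask_path)
  gt_path <- file.path(dir, paste0(prefix, "_ground_truth.json"))
  jsonlite::write_json(list(
    seed = gt$seed,
    design = unclass(gt$design),
    model = unclass(gt$model),
    sampling = list(voxel_mm = gt$sampling$voxel_mm,
                    smoothing_fwhm_mm = gt$sampling$smoothing_fwhm_mm),
    sheet = list(size_mm = gt$sheet$size_mm, mm_per_px = gt$sheet$mm_per_px,
                 od_period_mm = gt$sheet$od_period_mm,
                 sharpness = gt$sheet$sharpness,
                 coupling_rho = gt$sheet$coupling_rho, seed = gt$sheet$seed),
    condition_responses = lapply(gt$responses, as.numeric)
  ), gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mask_path, gt_path))
}
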