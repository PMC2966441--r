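# Forward model: stimulus -> neural response field -> voxel responses.

#' Neural response model parameters
#'
#' Parameterizes the forward model mapping a monocular grating stimulus to
#' the noise-free response of each sheet location, and the noise added per
#' acquired volume. The response of a location with ocularity `oc` (+1 left,
#' -1 right) and spatial-frequency preference `p` to a stimulus in eye `e`
#' (sign `s = +1` for L, `-1` for R) at stimulus frequency `f` on the same
#' unit preference axis is
#'
#' `r = base_gain * (1 + eye_selectivity * s * oc) *
#'      exp(-(f - p)^2 / (2 * sf_tuning_width^2)) + left_eye_offset_delta * [e == L]`
#'
#' The additive left-eye term models a global mean-signal advantage for
#' left-eye stimulation; the multiplicative term models monocular gain; the
#' Gaussian term is standard unimodal spatial-frequency tuning.
#'
#' @param base_gain Response of a fully preferred stimulus, arbitrary units.
#' @param eye_selectivity Gain modulation by ocularity in `[0, 1]`; 0 means
#'   binocular (no eye information).
#' @param sf_tuning_width SD of the Gaussian tuning over the unit
#'   spatial-frequency preference axis.
#' @param left_eye_offset_delta Additive response increment applied uniformly
#'   under left-eye stimulation.
#' @param noise_sd Stationary SD of per-volume voxel noise, in the same
#'   arbitrary units as `base_gain`.
#' @param ar1_phi AR(1) coefficient in `[0, 1)` of the temporal noise
#'   process (innovations scaled so the marginal SD stays `noise_sd`).
#' @param hrf `"double_gamma"` for the canonical hemodynamic response
#'   (6 s peak, 16 s undershoot) or `"boxcar"` for an idealized unit plateau
#'   used in exact tests.
#' @return An object of class `"response_model"`.
#' @export
response_model <- function(base_gain = 1,
                           eye_selectivity = 0.8,
                           sf_tuning_width = 0.2,
                           left_eye_offset_delta = 0.05,
                           noise_sd = 0.25,
                           ar1_phi = 0.3,
                           hrf = c("double_gamma", "boxcar")) {
  stopif_not_scalar_number(base_gain, "base_gain", min = 0)
  stopif_not_scalar_number(eye_selectivity, "eye_selectivity", min = 0, max = 1)
  stopif_not_scalar_number(sf_tuning_width, "sf_tuning_width", min = 1e-9)
  stopif_not_scalar_number(left_eye_offset_delta, "left_eye_offset_delta", min = 0)
  stopif_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stopif_not_scalar_number(ar1_phi, "ar1_phi", min = 0, max = 1 - 1e-9)
  structure(list(
    base_gain = base_gain,
    eye_selectivity = eye_selectivity,
    sf_tuning_width = sf_tuning_width,
    left_eye_offset_delta = left_eye_offset_delta,
    noise_sd = noise_sd,
    ar1_phi = ar1_phi,
    hrf = match.arg(hrf)
  ), class = "response_model")
}

# stimulus spatial frequencies on the unit preference axis
sf_axis_value <- function(sf) c(low = 0, high = 1)[[sf]]

#' Noise-free neural response of a sheet to a monocular grating
#'
#' Evaluates the forward model of [response_model()] at every sheet location
#' for one stimulus (eye of origin x spatial frequency).
#'
#' @param sheet A [cortical_sheet()].
#' @param eye `"L"` or `"R"`.
#' @param sf `"low"` or `"high"` (mapped to 0 and 1 on the unit preference
#'   axis), or a number in `[0, 1]`.
#' @param model A [response_model()].
#' @return Matrix of non-negative responses, same shape as the sheet fields.
#' @export
neural_response <- function(sheet, eye, sf, model = response_model()) {
  if (!inherits(sheet, "cortical_sheet")) stop("sheet must be a cortical_sheet")
  if (!eye %in% c("L", "R")) stop("unknown eye token: ", eye)
  f <- if (is.character(sf)) {
    if (!sf %in% c("low", "high")) stop("unknown sf token: ", sf)
    sf_axis_value(sf)
  } else {
    stopif_not_scalar_number(sf, "sf", min = 0, max = 1)
    sf
  }
  s <- if (eye == "L") 1 else -1
  gain <- model$base_gain * (1 + model$eye_selectivity * s * sheet$ocularity)
  tuning <- exp(-(f - sheet$sf_pref)^2 / (2 * model$sf_tuning_width^2))
  resp <- gain * tuning + if (eye == "L") model$left_eye_offset_delta else 0
  attr(resp, "mm_per_px") <- sheet$mm_per_px
  resp
}

#' Voxel sampling configuration
#'
#' @param voxel_mm Isotropic voxel edge length in mm (default 1.5); must be
#'   an integer multiple of the sheet's pixel size.
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM in mm applied to the
#'   response field before voxel averaging (default 4; 0 disables).
#' @param roi_mask Optional logical/integer vector selecting a subset of
#'   voxels (in column-major voxel-grid order) as the region of interest.
#' @return An object of class `"voxel_sampling"`.
#' @export
voxel_sampling <- function(voxel_mm = 1.5, smoothing_fwhm_mm = 4,
                           roi_mask = NULL) {
  stopif_not_scalar_number(voxel_mm, "voxel_mm", min = 1e-9)
  stopif_not_scalar_number(smoothing_fwhm_mm, "smoothing_fwhm_mm", min = 0)
  structure(list(voxel_mm = voxel_mm, smoothing_fwhm_mm = smoothing_fwhm_mm,
                 roi_mask = roi_mask), class = "voxel_sampling")
}

# Separable Gaussian smoothing with edge renormalization, so that a constant
# field stays exactly constant near the borders.
gaussian_smooth_field <- function(field, fwhm_mm, mm_per_px) {
  if (fwhm_mm <= 0) return(field)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / mm_per_px  # in pixels
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  smooth_1d <- function(m) {
    # convolve each column with k, renormalizing by the in-bounds kernel mass
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(field))))
}

#' Sample a sheet response field into voxels
#'
#' Models the partial-volume averaging by which an fMRI voxel grid samples
#' the much finer columnar architecture: the field is optionally smoothed
#' with a Gaussian kernel and then averaged within each voxel footprint.
#' Residual voxel-to-voxel differences after this averaging are the biased
#' sampling signal that pattern decoding relies on.
#'
#' @param field Response matrix with a `mm_per_px` attribute (from
#'   [neural_response()]), or a `cortical_sheet` field.
#' @param config A [voxel_sampling()].
#' @param mm_per_px Grid resolution override.
#' @return Numeric vector of voxel responses (column-major voxel order),
#'   restricted to `config$roi_mask` when given. Attribute `dim_vox` records
#'   the full voxel-grid dimensions.
#' @export
sample_voxels <- function(field, config = voxel_sampling(),
                          mm_per_px = attr(field, "mm_per_px")) {
  if (is.null(mm_per_px)) stop("field must carry a mm_per_px attribute")
  px_per_vox <- config$voxel_mm / mm_per_px
  if (abs(px_per_vox - round(px_per_vox)) > 1e-9) {
    stop("voxel_mm must be an integer multiple of the sheet pixel size")
  }
  px_per_vox <- as.integer(round(px_per_vox))
  nvx <- nrow(field) %/% px_per_vox
  nvy <- ncol(field) %/% px_per_vox
  if (nvx < 1L || nvy < 1L) stop("voxel footprint larger than the sheet")
  sm <- gaussian_smooth_field(field, config$smoothing_fwhm_mm, mm_per_px)
  sm <- sm[seq_len(nvx * px_per_vox), seq_len(nvy * px_per_vox), drop = FALSE]
  # block-average px_per_vox x px_per_vox footprints
  rowblk <- rowsum(sm, rep(seq_len(nvx), each = px_per_vox)) / px_per_vox
  colblk <- t(rowsum(t(rowblk), rep(seq_len(nvy), each = px_per_vox))) / px_per_vox
  v <- as.vector(colblk)
  if (!is.null(config$roi_mask)) v <- v[config$roi_mask]
  attr(v, "dim_vox") <- c(nvx, nvy)
  v
}
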