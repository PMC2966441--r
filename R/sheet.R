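# Simulated columnar maps on a flattened 2D patch of visual cortex.

# Isotropic band-pass filtered white noise: the standard minimal generative
# model for stripe-like columnar layouts. The filter is a log-Gaussian annulus
# in the 2D frequency plane centred on the columnar frequency.
bandpass_noise_field <- function(nx, ny, mm_per_px, period_mm,
                                 bandwidth_oct = 0.5) {
  noise <- matrix(stats::rnorm(nx * ny), nx, ny)
  # frequency grids in cycles/mm
  fx <- c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / (nx * mm_per_px)
  fy <- c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / (ny * mm_per_px)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  f0 <- 1 / period_mm
  filt <- matrix(0, nx, ny)
  nz <- fr > 0
  filt[nz] <- exp(-(log2(fr[nz] / f0))^2 / (2 * bandwidth_oct^2))
  field <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (nx * ny)
  field <- field - mean(field)
  field / stats::sd(as.vector(field))
}

#' Generate an ocular-dominance map
#'
#' Simulates the ocularity field of a flattened cortical patch as band-pass
#' filtered Gaussian white noise passed through a saturating nonlinearity.
#' The band-pass annulus is centred on the columnar spatial frequency
#' `1/od_period_mm`, producing an alternating left/right striped layout with
#' the chosen dominant period (one period covers one left-eye plus one
#' right-eye column, so the default 1.6 mm period gives ~0.8 mm columns,
#' the width of human ocular-dominance columns).
#'
#' @param size_mm Extent of the (square) sheet in mm. Must span at least two
#'   columnar periods; at least four are recommended for a stable spectrum.
#' @param mm_per_px Grid resolution in mm per pixel (default 0.1).
#' @param od_period_mm Dominant columnar period in mm (default 1.6).
#' @param sharpness Saturation strength `s >= 0`: the unit-variance band-passed
#'   field `z` is mapped through `tanh(s * z)`. `s = 0` means no saturation and
#'   the linear field is rescaled to the unit interval by its maximum absolute
#'   value.
#' @param seed Integer RNG seed; the same seed always yields the same map.
#' @return A matrix with values in `[-1, 1]`: +1 fully left-eye dominated,
#'   -1 fully right-eye dominated. Attribute `mm_per_px` records resolution.
#' @export
generate_od_map <- function(size_mm = 19.2, mm_per_px = 0.1,
                            od_period_mm = 1.6, sharpness = 2, seed = 1) {
  stopif_not_scalar_number(size_mm, "size_mm", min = 1e-9)
  stopif_not_scalar_number(od_period_mm, "od_period_mm", min = 1e-9)
  stopif_not_scalar_number(sharpness, "sharpness", min = 0)
  if (size_mm < 2 * od_period_mm) {
    stop("sheet must span at least 2 columnar periods; got ",
         format(size_mm / od_period_mm, digits = 3), call. = FALSE)
  }
  n <- as.integer(round(size_mm / mm_per_px))
  z <- with_seed(seed, bandpass_noise_field(n, n, mm_per_px, od_period_mm))
  oc <- if (sharpness == 0) z / max(abs(z)) else tanh(sharpness * z)
  attr(oc, "mm_per_px") <- mm_per_px
  oc
}

#' Radially averaged spatial power spectrum
#'
#' Averages the 2D power spectrum of a field over annuli of constant spatial
#' frequency. Used to verify that generated columnar maps concentrate power
#' at the columnar frequency.
#'
#' @param field Numeric matrix.
#' @param mm_per_px Grid resolution (taken from the field's attribute when
#'   present).
#' @return A data frame with columns `freq` (cycles/mm) and `power`.
#' @export
radial_power_spectrum <- function(field, mm_per_px = attr(field, "mm_per_px")) {
  if (is.null(mm_per_px)) stop("mm_per_px missing")
  nx <- nrow(field); ny <- ncol(field)
  p <- Mod(stats::fft(field - mean(field)))^2
  fx <- c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / (nx * mm_per_px)
  fy <- c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / (ny * mm_per_px)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  # bin by frequency at the grid's fundamental resolution
  df <- 1 / (nx * mm_per_px)
  bin <- round(fr / df)
  keep <- bin > 0
  pow <- tapply(p[keep], bin[keep], mean)
  data.frame(freq = as.numeric(names(pow)) * df, power = as.numeric(pow))
}

#' Generate a spatial-frequency preference map coupled to ocularity
#'
#' Builds a preference field on the unit interval (0 = lowest, 1 = highest
#' preferred spatial frequency) whose low-preference domains coincide with
#' the centres of ocular-dominance columns to a tunable degree. The field is
#' a weighted mixture of a `(1 - |ocularity|)`-derived component (low sf
#' preference at column centres, where `|ocularity|` is large) and
#' independent band-passed noise, rank-mapped to a uniform marginal on
#' `[0, 1]`.
#'
#' @param ocularity Ocularity matrix from [generate_od_map()].
#' @param coupling_rho Mixture weight in `[0, 1]`: 0 = independent of
#'   ocularity, 1 = deterministic function of `|ocularity|`.
#' @param period_mm Spatial scale of the independent noise component
#'   (default: same 1.6 mm scale as the columnar map).
#' @param seed Integer RNG seed.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
generate_sf_map <- function(ocularity, coupling_rho, period_mm = 1.6, seed = 1) {
  stopif_not_scalar_number(coupling_rho, "coupling_rho", min = 0, max = 1)
  mm_per_px <- attr(ocularity, "mm_per_px")
  if (is.null(mm_per_px)) stop("ocularity must carry a mm_per_px attribute")
  nx <- nrow(ocularity); ny <- ncol(ocularity)
  base <- 1 - abs(ocularity)
  zb <- (base - mean(base)) / stats::sd(as.vector(base))
  zn <- with_seed(seed, bandpass_noise_field(nx, ny, mm_per_px, period_mm))
  z <- coupling_rho * zb + (1 - coupling_rho) * zn
  sf <- matrix((rank(z, ties.method = "first") - 0.5) / length(z), nx, ny)
  attr(sf, "mm_per_px") <- mm_per_px
  sf
}

#' Simulate a full cortical sheet (ocularity + spatial-frequency preference)
#'
#' Convenience wrapper generating both columnar fields of one simulated
#' patch of early visual cortex.
#'
#' @inheritParams generate_od_map
#' @param coupling_rho Association strength in `[0, 1]` between low
#'   spatial-frequency preference and ocular-dominance column centres
#'   (see [generate_sf_map()]).
#' @param seed Integer master seed for both fields.
#' @return An object of class `"cortical_sheet"`: a list with matrices
#'   `ocularity` and `sf_pref` plus the generating parameters.
#' @export
cortical_sheet <- function(size_mm = 19.2, mm_per_px = 0.1,
                           od_period_mm = 1.6, sharpness = 2,
                           coupling_rho = 0.8, seed = 1) {
  oc <- generate_od_map(size_mm, mm_per_px, od_period_mm, sharpness,
                        seed = derive_seed(seed, 1))
  sf <- generate_sf_map(oc, coupling_rho, period_mm = od_period_mm,
                        seed = derive_seed(seed, 2))
  structure(list(
    ocularity = oc, sf_pref = sf,
    size_mm = size_mm, mm_per_px = mm_per_px,
    od_period_mm = od_period_mm, sharpness = sharpness,
    coupling_rho = coupling_rho, seed = seed
  ), class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("Cortical sheet %.1f x %.1f mm (%d x %d px at %.2f mm)\n",
              x$size_mm, x$size_mm, nrow(x$ocularity), ncol(x$ocularity),
              x$mm_per_px))
  cat(sprintf("  OD period %.2f mm, sharpness %.1f, sf coupling %.2f\n",
              x$od_period_mm, x$sharpness, x$coupling_rho))
  cat(sprintf("  ocularity mean %.3f; corr(1-sf, |oc|) = %.3f\n",
              mean(x$ocularity),
              stats::cor(1 - as.vector(x$sf_pref), abs(as.vector(x$ocularity)))))
  invisible(x)
}
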