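## CIE standard illuminant D65, relative spectral power, 300-650 nm / 10 nm.
d65_power <- c(
  0.0341, 3.2945, 20.2360, 37.0535, 39.9488, 44.9117, 46.6383, 52.0891,
  49.9755, 54.6482, 82.7549, 91.4860, 93.4318, 86.6823, 104.8650, 117.0080,
  117.8120, 114.8610, 115.9230, 108.8110, 109.3540, 107.8020, 104.7900,
  107.6890, 104.4050, 104.0460, 100.0000, 96.3342, 95.7880, 88.6856,
  90.0062, 89.5991, 87.6987, 83.2886, 83.6992, 80.0268)

#' Daylight illuminant (D65) as photon flux
#'
#' Open-sky daylight of correlated colour temperature 6500 K (CIE standard
#' illuminant D65) on the 300-650 nm model grid, converted from relative
#' spectral power to relative photon flux by multiplying by wavelength
#' (a photon's energy is hc/lambda, so photon count per unit power scales
#' with lambda). Absolute scale is arbitrary: von Kries adaptation cancels
#' any multiplicative factor.
#'
#' @param grid wavelength grid; values outside 300-650 nm are not available.
#' @return a [spectral_function()] of relative photon flux.
#' @export
make_illuminant <- function(grid = model_grid()) {
  d65 <- spectral_function(model_grid(), d65_power * model_grid())
  resample_spectrum(d65, grid)
}

#' Green-leaf adapting background
#'
#' A parametric average green-leaf reflectance used as the default adapting
#' background: low in the UV and blue, with the chlorophyll "green bump"
#' peaking near 550 nm and a mild rise toward the red edge. This is a
#' smooth stand-in for a field-averaged foliage spectrum (e.g. averaged
#' Eucalyptus canopy leaves); any measured background can be supplied to
#' [spectrum_to_locus()] instead.
#'
#' @param grid wavelength grid; default [model_grid()].
#' @return a [spectral_function()] with all values in (0, 0.6).
#' @export
make_leaf_background <- function(grid = model_grid()) {
  grid <- as.numeric(grid)
  v <- 0.04 +
    0.11 * exp(-0.5 * ((grid - 550) / 35)^2) +
    0.05 * stats::plogis((grid - 660) / 25)
  spectral_function(grid, v)
}
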