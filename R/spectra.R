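#' Tabulated spectral function
#'
#' Container for any function of wavelength used by the colour-vision model:
#' floral reflectance (fraction), photoreceptor sensitivity (0-1), background
#' reflectance, or illuminant photon flux (relative units). Values are stored
#' on a strictly increasing wavelength grid in nanometres.
#'
#' @param wavelength numeric, strictly increasing wavelengths in nm.
#' @param value numeric, non-negative values, same length as `wavelength`.
#' @return An object of class `spectral_function`: a list with elements
#'   `wavelength` and `value`.
#' @examples
#' sf <- spectral_function(seq(300, 650, 10), rep(0.5, 36))
#' @export
spectral_function <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 2L) stop("need at least 2 grid points", call. = FALSE)
  if (anyNA(wavelength) || anyNA(value)) stop("NA in spectral data", call. = FALSE)
  if (any(diff(wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (any(value < 0)) stop("spectral values must be non-negative", call. = FALSE)
  structure(list(wavelength = wavelength, value = value),
            class = "spectral_function")
}

#' @export
print.spectral_function <- function(x, ...) {
  cat(sprintf("<spectral_function: %d points, %g-%g nm, range [%.4g, %.4g]>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' The 10 nm model wavelength grid
#'
#' The hexagon colour model integrates all spectral functions from 300 to
#' 650 nm in 10 nm steps; this returns that grid (36 points).
#'
#' @return numeric vector `seq(300, 650, by = 10)`.
#' @export
model_grid <- function() seq(300, 650, by = 10)

#' Resample a spectral function onto a new grid
#'
#' Linear interpolation; the target grid must lie inside the measured range
#' (no extrapolation). Reflectance measured beyond 650 nm is simply truncated
#' by resampling onto [model_grid()]. Resampling onto the spectrum's own grid
#' is lossless.
#'
#' @param sf a [spectral_function()].
#' @param grid target wavelengths (nm), strictly increasing.
#' @return a `spectral_function` on `grid`.
#' @export
resample_spectrum <- function(sf, grid = model_grid()) {
  stopifnot(inherits(sf, "spectral_function"))
  grid <- as.numeric(grid)
  if (min(grid) < min(sf$wavelength) || max(grid) > max(sf$wavelength)) {
    stop(sprintf("spectrum covers %g-%g nm but %g-%g nm requested",
                 min(sf$wavelength), max(sf$wavelength), min(grid), max(grid)),
         call. = FALSE)
  }
  if (identical(sf$wavelength, grid)) return(sf)
  v <- stats::approx(sf$wavelength, sf$value, xout = grid, method = "linear")$y
  spectral_function(grid, v)
}

#' Average several spectra pointwise
#'
#' Replicate flower measurements of one species are averaged into a single
#' species-level spectrum. Spectra on different grids are first resampled
#' onto `grid`.
#'
#' @param spectra a non-empty list of [spectral_function()]s.
#' @param grid common grid; defaults to the grid of the first spectrum when
#'   all grids agree, otherwise [model_grid()].
#' @return the mean `spectral_function`.
#' @export
average_spectra <- function(spectra, grid = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("need at least one spectrum", call. = FALSE)
  }
  if (is.null(grid)) {
    same <- all(vapply(spectra, function(s)
      identical(s$wavelength, spectra[[1L]]$wavelength), logical(1)))
    grid <- if (same) spectra[[1L]]$wavelength else model_grid()
  }
  mats <- vapply(spectra, function(s) resample_spectrum(s, grid)$value,
                 numeric(length(grid)))
  spectral_function(grid, rowMeans(as.matrix(mats)))
}

#' Visual pigment absorbance template (vitamin A1)
#'
#' Rhodopsin alpha-band absorbance as a function of wavelength for a pigment
#' with peak absorbance `lambda_max`, following the widely used A1 template
#' of Govardovskii et al. (2000), optionally adding the short-wavelength
#' beta band. The curve is normalised to a maximum of 1 on the grid.
#'
#' @param lambda_max peak wavelength in nm, between 300 and 600.
#' @param grid wavelength grid (nm); defaults to [model_grid()].
#' @param beta logical, include the beta band (default `FALSE`).
#' @return a [spectral_function()] with maximum value 1 at the grid point
#'   nearest `lambda_max`.
#' @export
a1_template <- function(lambda_max, grid = model_grid(), beta = FALSE) {
  stop_if_not_scalar_number(lambda_max, "lambda_max")
  if (lambda_max < 300 || lambda_max > 600) {
    stop("lambda_max must lie in [300, 600] nm", call. = FALSE)
  }
  grid <- as.numeric(grid)
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  v <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    v <- v + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  spectral_function(grid, v / max(v))
}
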