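#' Hymenopteran trichromatic receptor set
#'
#' The generalised hymenopteran visual system: three photoreceptor classes
#' with sensitivity peaks at 350 nm (UV), 440 nm (blue, B) and 540 nm
#' (green, G), each built from the A1 pigment template ([a1_template()]).
#'
#' @param grid wavelength grid; defaults to [model_grid()].
#' @param beta include the template beta band (default `FALSE`).
#' @return a named list of class `receptor_set` with elements `UV`, `B`, `G`,
#'   each a [spectral_function()].
#' @export
bee_receptors <- function(grid = model_grid(), beta = FALSE) {
  structure(list(UV = a1_template(350, grid, beta),
                 B  = a1_template(440, grid, beta),
                 G  = a1_template(540, grid, beta)),
            class = "receptor_set")
}

## Riemann-sum integral of a product of spectral functions on a common
## uniform grid. The step size cancels between photon capture and the von
## Kries coefficient, but is applied for dimensional honesty.
check_common_grid <- function(...) {
  fns <- list(...)
  g <- fns[[1L]]$wavelength
  for (f in fns[-1L]) {
    if (!isTRUE(all.equal(f$wavelength, g))) {
      stop("spectral functions are on different wavelength grids", call. = FALSE)
    }
  }
  steps <- diff(g)
  if (max(steps) - min(steps) > 1e-9 * max(steps)) {
    stop("wavelength grid must be uniform for Riemann integration", call. = FALSE)
  }
  g
}

riemann_product <- function(...) {
  fns <- list(...)
  g <- do.call(check_common_grid, fns)
  prod_v <- Reduce(`*`, lapply(fns, `[[`, "value"))
  sum(prod_v) * (g[2L] - g[1L])
}

#' von Kries adaptation coefficient
#'
#' The reciprocal of a receptor's photon catch from the adapting background:
#' R_i = 1 / integral of S_i(lambda) I_B(lambda) D(lambda), so that the
#' background itself always yields a photon capture of exactly 1 in every
#' receptor. Integration is a Riemann sum on the common uniform grid.
#'
#' @param S receptor sensitivity, a [spectral_function()].
#' @param background background reflectance I_B.
#' @param illuminant illuminant photon flux D.
#' @return a positive scalar.
#' @export
von_kries_coefficient <- function(S, background, illuminant) {
  denom <- riemann_product(S, background, illuminant)
  if (!is.finite(denom) || denom <= 1e-300) {
    stop("degenerate background: receptor catch from the background is zero",
         call. = FALSE)
  }
  1 / denom
}

#' Relative photon capture
#'
#' P_i = R_i * integral of S_i(lambda) I(lambda) D(lambda): the background-
#' normalised photon catch of receptor i viewing a stimulus with reflectance
#' I under illuminant D. By construction P = 1 when I equals the adapting
#' background.
#'
#' @param S receptor sensitivity.
#' @param stimulus stimulus reflectance I.
#' @param illuminant illuminant photon flux D.
#' @param R von Kries coefficient from [von_kries_coefficient()], computed
#'   with the same receptor, background and illuminant.
#' @return non-negative scalar P.
#' @export
photon_capture <- function(S, stimulus, illuminant, R) {
  stop_if_not_scalar_number(R, "R")
  R * riemann_product(S, stimulus, illuminant)
}

#' Receptor excitation
#'
#' Saturating phototransduction E = P / (P + 1), mapping photon captures to
#' excitations in [0, 1) with half-saturation at the adapting background
#' (P = 1 gives E = 0.5).
#'
#' @param P non-negative photon capture(s).
#' @return excitation(s) in [0, 1).
#' @export
excitation <- function(P) {
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("photon capture must be finite and non-negative", call. = FALSE)
  }
  P / (P + 1)
}

#' Hexagon colour-space coordinates
#'
#' Projects the three receptor excitations onto the colour hexagon:
#' x = sin(60 deg) (E_G - E_UV), y = E_B - 0.5 (E_G + E_UV). The adapting
#' background (all E = 0.5) maps to the origin; the pure-receptor triples
#' map to vertices at distance 1.
#'
#' Some published statements of the y axis carry a typographic sign slip
#' (y = E_B - 0.5(E_G - E_UV)), which would displace the adapting background
#' to y = 0.5; the form used here keeps the background at the centre, as the
#' hexagon model requires.
#'
#' @param E_UV,E_B,E_G receptor excitations in [0, 1].
#' @return numeric vector `c(x = , y = )`.
#' @export
hexagon_coords <- function(E_UV, E_B, E_G) {
  for (e in list(E_UV, E_B, E_G)) {
    if (!is.finite(e) || e < 0 || e > 1) {
      stop("excitations must lie in [0, 1]", call. = FALSE)
    }
  }
  c(x = sin(pi / 3) * (E_G - E_UV), y = E_B - 0.5 * (E_G + E_UV))
}

#' Hue angle and chromatic contrast of a hexagon locus
#'
#' Polar coordinates of a colour locus: chromatic contrast is the Euclidean
#' distance from the hexagon centre (the adapting background); hue is the
#' angle measured counter-clockwise with the blue vertex (0, 1) at 90
#' degrees. Loci closer to the centre than `achromatic_eps` have no defined
#' hue (returned as `NA`), never a spurious 0 degrees.
#'
#' @param x,y hexagon coordinates.
#' @param achromatic_eps contrast below which hue is undefined (default 1e-9).
#' @return list with `hue_deg` (in [0, 360) or `NA`) and `contrast`.
#' @export
hue_and_contrast <- function(x, y, achromatic_eps = 1e-9) {
  contrast <- sqrt(x^2 + y^2)
  hue <- if (contrast < achromatic_eps) NA_real_ else {
    (atan2(y, x) * 180 / pi) %% 360
  }
  list(hue_deg = hue, contrast = contrast)
}

#' Colour-category sectors of the hexagon
#'
#' The six 60-degree hue sectors of bee colour space, in counter-clockwise
#' order starting from hue 0: BG, B, UB, U, UG, G.
#'
#' @return character vector of sector labels.
#' @export
hexagon_sectors <- function() c("B", "BG", "G", "UG", "U", "UB")

#' Classify a hue angle into a colour category
#'
#' Assigns a hue angle to one of the six standard bee colour categories:
#' BLUE (B), BLUE-GREEN (BG), GREEN (G), UV-GREEN (UG), UV (U) and UV-BLUE
#' (UB). Sectors are 60 degrees wide with the BLUE sector centred on the
#' blue vertex at 90 degrees: BG = [0, 60), B = [60, 120), UB = [120, 180),
#' U = [180, 240), UG = [240, 300), G = [300, 360). A boundary hue belongs
#' to the counter-clockwise (upper) sector.
#'
#' @param hue_deg hue angle(s) in degrees; `NA` (achromatic) is an error.
#' @return factor of sector labels with levels `hexagon_sectors()`.
#' @export
classify_sector <- function(hue_deg) {
  if (anyNA(hue_deg)) {
    stop("cannot classify an achromatic locus (undefined hue)", call. = FALSE)
  }
  h <- hue_deg %% 360
  labels <- c("BG", "B", "UB", "U", "UG", "G")
  factor(labels[floor(h / 60) + 1L], levels = hexagon_sectors())
}

#' Convert a reflectance spectrum to a hexagon colour locus
#'
#' Full colour-vision pipeline: von Kries coefficients from the background,
#' photon captures of the stimulus, excitations, hexagon coordinates, polar
#' hue/contrast and colour category.
#'
#' @param stimulus stimulus reflectance, a [spectral_function()] (resampled
#'   onto the grid of `receptors` if necessary).
#' @param background adapting background reflectance; default
#'   [make_leaf_background()].
#' @param illuminant illuminant photon flux; default [make_illuminant()].
#' @param receptors a [bee_receptors()] set.
#' @param achromatic_eps see [hue_and_contrast()].
#' @return an object of class `colour_locus`: list with `E_UV`, `E_B`, `E_G`,
#'   `x`, `y`, `hue_deg`, `contrast`, `sector` (`NA` at the achromatic point).
#' @export
spectrum_to_locus <- function(stimulus,
                              background = make_leaf_background(),
                              illuminant = make_illuminant(),
                              receptors = bee_receptors(),
                              achromatic_eps = 1e-9) {
  grid <- receptors$UV$wavelength
  stimulus <- resample_spectrum(stimulus, grid)
  background <- resample_spectrum(background, grid)
  illuminant <- resample_spectrum(illuminant, grid)
  E <- vapply(receptors[c("UV", "B", "G")], function(S) {
    R <- von_kries_coefficient(S, background, illuminant)
    excitation(photon_capture(S, stimulus, illuminant, R))
  }, numeric(1))
  xy <- hexagon_coords(E[["UV"]], E[["B"]], E[["G"]])
  pol <- hue_and_contrast(xy[["x"]], xy[["y"]], achromatic_eps)
  sector <- if (is.na(pol$hue_deg)) NA_character_ else
    as.character(classify_sector(pol$hue_deg))
  structure(list(E_UV = E[["UV"]], E_B = E[["B"]], E_G = E[["G"]],
                 x = xy[["x"]], y = xy[["y"]],
                 hue_deg = pol$hue_deg, contrast = pol$contrast,
                 sector = sector),
            class = "colour_locus")
}

#' @export
print.colour_locus <- function(x, ...) {
  cat(sprintf(
    "<colour_locus: E=(%.3f, %.3f, %.3f)  xy=(%.3f, %.3f)  hue=%s  contrast=%.3f  sector=%s>\n",
    x$E_UV, x$E_B, x$E_G, x$x, x$y,
    if (is.na(x$hue_deg)) "undef" else sprintf("%.1f", x$hue_deg),
    x$contrast, if (is.na(x$sector)) "undef" else x$sector))
  invisible(x)
}
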