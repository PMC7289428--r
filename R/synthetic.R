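#' Floral reflectance archetypes
#'
#' A small library of smooth parametric petal-reflectance shapes built from
#' three components: a long-pass sigmoid plateau (inflection, slope, height),
#' an optional Gaussian peak, and an optional UV bump centred at 350 nm.
#' The archetypes are chosen to cover the hexagon colour categories under
#' the default leaf background and daylight illuminant, with the UV sector
#' reachable but rare, as in natural floral communities.
#'
#' @return named list of archetype parameter lists; each has `name`,
#'   `sigmoid_infl`, `sigmoid_slope`, `plateau`, `peak_centre`,
#'   `peak_width`, `peak_height`, `uv_height`, and `sector`, the colour
#'   category the archetype produces at zero jitter under defaults.
#' @export
flower_archetypes <- function() {
  arch <- function(name, infl, slope, plateau, pc = NA, pw = NA, ph = 0,
                   uv = 0, sector) {
    list(name = name, sigmoid_infl = infl, sigmoid_slope = slope,
         plateau = plateau, peak_centre = pc, peak_width = pw,
         peak_height = ph, uv_height = uv, sector = sector)
  }
  list(
    blue = arch("blue", 620, 30, 0.25, pc = 450, pw = 35, ph = 0.45,
                sector = "B"),
    uv_absorbing_white = arch("uv_absorbing_white", 420, 18, 0.85,
                              sector = "BG"),
    yellow = arch("yellow", 510, 15, 0.80, sector = "G"),
    uv_yellow = arch("uv_yellow", 510, 15, 0.80, uv = 0.35, sector = "UG"),
    uv_dark = arch("uv_dark", 640, 40, 0.10, uv = 0.45, sector = "U"),
    uv_blue = arch("uv_blue", 630, 40, 0.15, pc = 440, pw = 40, ph = 0.50,
                   uv = 0.50, sector = "UB")
  )
}

archetype_reflectance <- function(archetype, grid = model_grid()) {
  g <- as.numeric(grid)
  v <- 0.03 +
    archetype$plateau * stats::plogis((g - archetype$sigmoid_infl) /
                                        archetype$sigmoid_slope)
  if (!is.na(archetype$peak_centre) && archetype$peak_height > 0) {
    v <- v + archetype$peak_height *
      exp(-0.5 * ((g - archetype$peak_centre) / archetype$peak_width)^2)
  }
  if (archetype$uv_height > 0) {
    v <- v + archetype$uv_height * exp(-0.5 * ((g - 350) / 25)^2)
  }
  pmin(pmax(v, 0), 1)
}

#' Generate a flower reflectance spectrum from an archetype
#'
#' Evaluates the archetype's parametric curve on the grid and applies a
#' smooth multiplicative jitter (log-normal deviations interpolated from
#' 50 nm knots), keeping reflectance in [0, 1]. Zero jitter gives the
#' deterministic archetype curve; a fixed seed gives a reproducible flower.
#'
#' @param archetype one element of [flower_archetypes()].
#' @param jitter standard deviation of the log-scale perturbation
#'   (default 0.08).
#' @param seed optional integer seed.
#' @param grid wavelength grid.
#' @return a [spectral_function()].
#' @export
make_flower_spectrum <- function(archetype, jitter = 0.08, seed = NULL,
                                 grid = model_grid()) {
  base <- archetype_reflectance(archetype, grid)
  if (jitter <= 0) return(spectral_function(grid, base))
  v <- with_seed(seed, {
    knots <- seq(min(grid), max(grid), by = 50)
    bumps <- stats::rnorm(length(knots), 0, jitter)
    base * exp(stats::approx(knots, bumps, xout = grid, rule = 2)$y)
  })
  spectral_function(grid, pmin(pmax(v, 0), 1))
}

#' Specification of a synthetic floral community
#'
#' Parameters of the community generator: number of species, the target
#' mix of colour sectors, family composition, site labels, and the
#' log-normal per-flower sugar model. Defaults describe a 59-species
#' Australian-style woodland community: colour sectors dominated by
#' blue-green and blue with a single UV species, 28 orchids and 3 asters,
#' and right-skewed sugar amounts with a median of about 392 ug per
#' flower. `effect` gives multiplicative sector offsets of the sugar
#' location (all 1 = no colour/reward association, the null community).
#'
#' @param n_species number of species.
#' @param sector_counts named integer vector over
#'   [hexagon_sectors()], summing to `n_species`.
#' @param n_asteraceae,n_orchidaceae species assigned to Asteraceae /
#'   Orchidaceae (never the UV-sector species).
#' @param sugar_meanlog,sugar_sdlog log-normal parameters of per-flower
#'   sugar (ug).
#' @param effect named multiplicative sugar offsets per sector.
#' @param jitter spectral jitter passed to [make_flower_spectrum()].
#' @param seed integer seed.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(n_species = 59,
                           sector_counts = c(B = 12, BG = 20, G = 12,
                                             UG = 10, U = 1, UB = 4),
                           n_asteraceae = 3, n_orchidaceae = 28,
                           sugar_meanlog = log(392), sugar_sdlog = 1,
                           effect = c(B = 1, BG = 1, G = 1, UG = 1,
                                      U = 1, UB = 1),
                           jitter = 0.08, seed = 1L) {
  if (sum(sector_counts) != n_species) {
    stop("sector_counts must sum to n_species", call. = FALSE)
  }
  if (!all(names(sector_counts) %in% hexagon_sectors())) {
    stop("unknown sector in sector_counts", call. = FALSE)
  }
  if (n_asteraceae + n_orchidaceae > n_species - sum(sector_counts["U"], na.rm = TRUE)) {
    stop("not enough non-UV species for the requested families", call. = FALSE)
  }
  structure(list(n_species = n_species, sector_counts = sector_counts,
                 n_asteraceae = n_asteraceae, n_orchidaceae = n_orchidaceae,
                 sugar_meanlog = sugar_meanlog, sugar_sdlog = sugar_sdlog,
                 effect = effect, jitter = jitter, seed = seed),
            class = "community_spec")
}

#' Generate a synthetic floral community
#'
#' Draws one flower spectrum per species from the archetype matching its
#' target colour sector, verifies the realised sector through the full
#' colour-vision model (rejection-sampling the jittered spectrum until the
#' target sector is hit), assigns families and sites, and draws per-flower
#' sugar from the sector-offset log-normal model. Everything is a pure
#' function of `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @param max_tries rejection-sampling cap per species before failing.
#' @return list with `records` (data frame: species, family, site,
#'   sugar_ug, E_UV, E_B, E_G, x, y, hue_deg, contrast, sector) and
#'   `spectra` (named list of [spectral_function()]s).
#' @export
make_community <- function(spec = community_spec(), max_tries = 200L) {
  stopifnot(inherits(spec, "community_spec"))
  archetypes <- flower_archetypes()
  by_sector <- split(archetypes, vapply(archetypes, `[[`, "", "sector"))
  targets <- rep(names(spec$sector_counts), spec$sector_counts)
  missing_arch <- setdiff(unique(targets), names(by_sector))
  if (length(missing_arch)) {
    stop("no archetype produces sector(s): ",
         paste(missing_arch, collapse = ", "), call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_species
    records <- vector("list", n)
    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      target <- targets[i]
      arch <- by_sector[[target]][[1L]]
      locus <- NULL
      for (try in seq_len(max_tries)) {
        sf <- make_flower_spectrum(arch, jitter = spec$jitter)
        loc <- spectrum_to_locus(sf)
        if (identical(loc$sector, target)) { locus <- loc; break }
      }
      if (is.null(locus)) {
        stop(sprintf("could not realise a %s-sector flower in %d tries",
                     target, max_tries), call. = FALSE)
      }
      spectra[[i]] <- sf
      mu <- spec$sugar_meanlog + log(spec$effect[[target]])
      records[[i]] <- data.frame(
        species = sprintf("sp_%02d", i), family = NA_character_,
        site = NA_character_,
        sugar_ug = stats::rlnorm(1, mu, spec$sugar_sdlog),
        E_UV = locus$E_UV, E_B = locus$E_B, E_G = locus$E_G,
        x = locus$x, y = locus$y, hue_deg = locus$hue_deg,
        contrast = locus$contrast, sector = locus$sector,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, records)
    names(spectra) <- records$species
    ## family assignment: the UV species stays outside the two excluded
    ## families so subset sizes behave like the field data
    non_uv <- which(records$sector != "U")
    fam_pool <- sample(non_uv)
    orch <- fam_pool[seq_len(spec$n_orchidaceae)]
    aster <- fam_pool[spec$n_orchidaceae + seq_len(spec$n_asteraceae)]
    other_fams <- c("Fabaceae", "Myrtaceae", "Goodeniaceae", "Ericaceae",
                    "Rutaceae", "Campanulaceae", "Clusiaceae")
    records$family <- sample(other_fams, nrow(records), replace = TRUE)
    records$family[orch] <- "Orchidaceae"
    records$family[aster] <- "Asteraceae"
    records$site <- sample(c("BM", "BW"), nrow(records), replace = TRUE)
    list(records = records, spectra = spectra)
  })
}

#' Simulate a tree and a lambda-structured trait
#'
#' Pure-birth (Yule) ultrametric tree with `n_tips` tips, plus a continuous
#' trait drawn from the multivariate normal with covariance
#' sigma2 * lambda-transform of the tree's Brownian covariance. lambda = 1
#' is Brownian motion; lambda = 0 makes tips independent.
#'
#' @param n_tips number of tips (>= 4).
#' @param lambda phylogenetic signal in [0, 1] used for simulation.
#' @param sigma2 Brownian rate.
#' @param seed integer seed.
#' @param root trait value at the root (default 0).
#' @return list with `tree` (ape::phylo) and `trait` (named vector).
#' @export
simulate_tree_and_trait <- function(n_tips, lambda = 1, sigma2 = 1,
                                    seed = NULL, root = 0) {
  if (n_tips < 4L) stop("need n_tips >= 4", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    C <- lambda_transform(phylo_vcv(tree), lambda)
    L <- chol(sigma2 * C)
    trait <- drop(root + t(L) %*% stats::rnorm(n_tips))
    names(trait) <- rownames(C)
    list(tree = tree, trait = trait)
  })
}

#' Write a complete synthetic study bundle to disk
#'
#' Materialises one synthetic study: long-form spectra CSV, species records
#' CSV, a pure-birth newick tree over the community's species (trait values
#' are the community's sugar contents), and a JSON manifest of every
#' parameter and seed.
#'
#' @param dir output directory (created if needed).
#' @param spec a [community_spec()].
#' @return invisibly, the list of file paths written.
#' @export
write_synthetic_bundle <- function(dir, spec = community_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comm <- make_community(spec)
  spectra_df <- do.call(rbind, lapply(names(comm$spectra), function(sp) {
    sf <- comm$spectra[[sp]]
    data.frame(species = sp, patch = 1L, wavelength_nm = sf$wavelength,
               reflectance_pct = 100 * sf$value)
  }))
  tree <- with_seed(spec$seed + 1L,
                    ape::rphylo(spec$n_species, birth = 1, death = 0))
  tree$tip.label <- comm$records$species
  paths <- list(
    spectra = file.path(dir, "spectra.csv"),
    records = file.path(dir, "records.csv"),
    tree = file.path(dir, "tree.nwk"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.csv(spectra_df, paths$spectra, row.names = FALSE)
  utils::write.csv(comm$records, paths$records, row.names = FALSE)
  ape::write.tree(tree, paths$tree)
  jsonlite::write_json(
    list(generator = "hexflora synthetic bundle",
         parameters = unclass(spec)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
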