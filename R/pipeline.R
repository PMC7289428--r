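#' Read floral reflectance spectra from CSV
#'
#' Accepts either the long form (columns `species`, optional `patch`,
#' `wavelength_nm`, `reflectance_pct` or `reflectance`) or the wide form
#' (first column `wavelength_nm`, one column per species). Reflectance may
#' be percent (0-100) or fraction (0-1); the unit is auto-detected from the
#' maximum value (> 1.5 means percent) unless overridden.
#'
#' @param path CSV path.
#' @param unit `"auto"`, `"percent"` or `"fraction"`.
#' @return named list of [spectral_function()]s, one per species (patch
#'   spectra of one species are averaged via [average_spectra()]).
#' @export
read_spectra_csv <- function(path, unit = c("auto", "percent", "fraction")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  long <- all(c("species", "wavelength_nm") %in% names(df))
  if (!long && names(df)[1L] != "wavelength_nm") {
    stop("unrecognised spectra CSV layout (need long or wide form)",
         call. = FALSE)
  }
  if (long) {
    vcol <- intersect(c("reflectance_pct", "reflectance"), names(df))[1L]
    if (is.na(vcol)) stop("no reflectance column found", call. = FALSE)
    vals <- df[[vcol]]
  } else {
    vals <- unlist(df[-1L], use.names = FALSE)
  }
  scale <- switch(unit,
                  percent = 100,
                  fraction = 1,
                  auto = if (max(vals, na.rm = TRUE) > 1.5) 100 else 1)
  if (long) {
    if (!"patch" %in% names(df)) df$patch <- 1L
    out <- lapply(split(df, df$species), function(d) {
      patches <- lapply(split(d, d$patch), function(p) {
        p <- p[order(p$wavelength_nm), ]
        spectral_function(p$wavelength_nm, p[[vcol]] / scale)
      })
      average_spectra(patches)
    })
  } else {
    wl <- df[[1L]]
    out <- lapply(df[-1L], function(v) spectral_function(wl, v / scale))
  }
  out
}

#' Compute colour loci for a set of species spectra
#'
#' Applies [spectrum_to_locus()] to each spectrum and assembles the results
#' into a data frame in the layout of the species-table dialect.
#'
#' @param spectra named list of [spectral_function()]s.
#' @inheritParams spectrum_to_locus
#' @return data frame: species, E_UV, E_B, E_G, x, y, hue_deg, contrast,
#'   sector.
#' @export
loci_table <- function(spectra,
                       background = make_leaf_background(),
                       illuminant = make_illuminant(),
                       receptors = bee_receptors()) {
  rows <- lapply(names(spectra), function(sp) {
    loc <- spectrum_to_locus(spectra[[sp]], background, illuminant, receptors)
    data.frame(species = sp, E_UV = loc$E_UV, E_B = loc$E_B, E_G = loc$E_G,
               x = loc$x, y = loc$y, hue_deg = loc$hue_deg,
               contrast = loc$contrast, sector = loc$sector,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a species record table
#'
#' Reads the species-table CSV: columns `species`, `family`, `sugar_ug`
#' (and optionally `site`), plus precomputed hexagon coordinates `x`, `y`
#' (the published-supplement dialect). Hue, contrast and sector are always
#' recomputed from `(x, y)` so the sector convention is uniform. A sugar
#' column whose maximum is below 10 is flagged as probably being in mg
#' rather than ug.
#'
#' @param path CSV path.
#' @return data frame of species records ready for
#'   [run_reward_analysis()].
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "family", "sugar_ug", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("records CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$sugar_ug)) stop("sugar_ug must be numeric", call. = FALSE)
  if (max(df$sugar_ug, na.rm = TRUE) < 10) {
    warning("sugar_ug maximum is < 10: values may be in mg, not ug",
            call. = FALSE)
  }
  if (!"site" %in% names(df)) df$site <- NA_character_
  pol <- Map(hue_and_contrast, df$x, df$y)
  df$hue_deg <- vapply(pol, `[[`, numeric(1), "hue_deg")
  df$contrast <- vapply(pol, `[[`, numeric(1), "contrast")
  df$sector <- ifelse(is.na(df$hue_deg), NA_character_,
                      as.character(classify_sector(
                        ifelse(is.na(df$hue_deg), 0, df$hue_deg))))
  df
}

#' Run the full colour/reward/phylogeny pipeline
#'
#' Orchestrates every analysis stage that its inputs allow: spectra are
#' converted to colour loci (skipped when a precomputed species table is
#' given, which takes precedence); the reward analysis runs over the
#' nested subsets; and, when a tree is supplied, Pagel's lambda is fitted
#' to sugar content with and without the Asteraceae. Outputs are written
#' as CSV/JSON into `outdir` together with a plain-text log of every
#' exclusion and seed.
#'
#' @param records_csv path to a species table CSV (see [read_records()]);
#'   takes precedence over `spectra_csv` for loci.
#' @param spectra_csv path to a spectra CSV (see [read_spectra_csv()]);
#'   requires `species_csv` giving `species`, `family`, `sugar_ug`
#'   (and optionally `site`) to attach rewards.
#' @param species_csv companion table for `spectra_csv`.
#' @param tree_file newick/nexus tree path, or `NULL` to skip the
#'   phylogenetic stage.
#' @param outdir output directory.
#' @param n_sim Monte-Carlo simulations for the contingency tests.
#' @param seed integer seed for all randomness.
#' @param mad_constant see [median_mad()].
#' @param lambda_test `"LR"` or `"permutation"`.
#' @param n_perm permutations when `lambda_test = "permutation"`.
#' @return invisibly, a list with `records`, `reward` (a `reward_report`),
#'   `phylo` (list or `NULL`), and `files` written.
#' @export
run_all <- function(records_csv = NULL, spectra_csv = NULL,
                    species_csv = NULL, tree_file = NULL,
                    outdir = ".", n_sim = 100000L, seed = 1L,
                    mad_constant = 1.4826,
                    lambda_test = c("LR", "permutation"), n_perm = 999L) {
  lambda_test <- match.arg(lambda_test)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (!is.null(records_csv)) {
    if (!is.null(spectra_csv)) {
      say("both species table and spectra supplied: using the precomputed (x, y) loci from %s",
          records_csv)
    }
    records <- read_records(records_csv)
  } else if (!is.null(spectra_csv)) {
    if (is.null(species_csv)) {
      stop("spectra_csv requires species_csv with sugar and family data",
           call. = FALSE)
    }
    spectra <- read_spectra_csv(spectra_csv)
    loci <- loci_table(spectra)
    meta <- utils::read.csv(species_csv, stringsAsFactors = FALSE)
    records <- merge(meta, loci, by = "species")
    say("computed %d colour loci from spectra", nrow(loci))
  } else {
    stop("supply records_csv or spectra_csv", call. = FALSE)
  }
  say("loaded %d species records; seed = %d, n_sim = %d",
      nrow(records), seed, n_sim)

  files <- list()
  loci_path <- file.path(outdir, "loci.csv")
  utils::write.csv(records, loci_path, row.names = FALSE)
  files$loci <- loci_path

  uv_n <- sum(records$sector == "U", na.rm = TRUE)
  say("excluding %d UV-sector species for SS1; %d Asteraceae for SS2; %d Orchidaceae for SS3",
      uv_n, sum(records$family == "Asteraceae"),
      sum(records$family == "Orchidaceae"))
  reward <- run_reward_analysis(records, n_sim = n_sim, seed = seed,
                                mad_constant = mad_constant)

  stats_rows <- lapply(names(reward$subsets), function(nm) {
    s <- reward$subsets[[nm]]
    if (identical(s$n, 0L)) return(NULL)
    data.frame(subset = nm, n = s$n, median_ug = s$median, mad_ug = s$mad,
               tau = s$tau$tau, tau_p = s$tau$p,
               chisq = if (is.null(s$contingency)) NA_real_ else s$contingency$chisq,
               chisq_p_mc = if (is.null(s$contingency)) NA_real_ else s$contingency$p_mc)
  })
  stats_path <- file.path(outdir, "subset_stats.csv")
  utils::write.csv(do.call(rbind, stats_rows), stats_path, row.names = FALSE)
  files$subset_stats <- stats_path

  cont <- lapply(reward$subsets[c("SS1", "SS2", "SS3")], function(s) {
    if (is.null(s$contingency)) return(NULL)
    ct <- s$contingency
    list(table = unname(ct$table), sectors = colnames(ct$table),
         chisq = ct$chisq, p_mc = ct$p_mc,
         n_sim = ct$n_sim, seed = seed, threshold_ug = s$threshold)
  })
  cont_path <- file.path(outdir, "contingency.json")
  jsonlite::write_json(cont, cont_path, auto_unbox = TRUE, digits = NA)
  files$contingency <- cont_path

  phylo <- NULL
  if (!is.null(tree_file)) {
    tree <- read_tree(tree_file)
    trait <- stats::setNames(records$sugar_ug, records$species)
    fit_one <- function(tr) {
      fit <- fit_lambda(tr, tree)
      p <- if (lambda_test == "LR") fit$p_value else
        lambda_significance(tr, tree, "permutation", n_perm, seed)
      list(lambda = fit$lambda, sigma2 = fit$sigma2, loglik = fit$loglik,
           loglik0 = fit$loglik0, p_value = p, method = lambda_test,
           n_tips = fit$n_tips)
    }
    no_aster <- records$family != "Asteraceae"
    phylo <- list(full = fit_one(trait),
                  no_asteraceae = fit_one(trait[no_aster]))
    say("lambda (full) = %.3f (p = %.3g); lambda (no Asteraceae) = %.3f (p = %.3g)",
        phylo$full$lambda, phylo$full$p_value,
        phylo$no_asteraceae$lambda, phylo$no_asteraceae$p_value)
    phylo_path <- file.path(outdir, "phylo_signal.json")
    jsonlite::write_json(phylo, phylo_path, auto_unbox = TRUE, digits = NA)
    files$phylo <- phylo_path
  } else {
    say("no tree supplied: phylogenetic-signal stage skipped")
  }

  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  files$log <- log_path
  invisible(list(records = records, reward = reward, phylo = phylo,
                 files = files))
}
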