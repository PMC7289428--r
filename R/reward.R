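#' Median and median absolute deviation
#'
#' Robust location/scale summary used to dichotomise floral sugar content:
#' the sample median and the median absolute deviation about it, scaled by
#' `mad_constant` (default 1.4826, the factor that makes the MAD consistent
#' for a normal distribution; set to 1 for the raw MAD).
#'
#' @param values numeric vector with at least one finite value.
#' @param mad_constant scale factor applied to the raw MAD.
#' @return named numeric vector `c(median = , mad = )`.
#' @export
median_mad <- function(values, mad_constant = 1.4826) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values", call. = FALSE)
  m <- stats::median(values)
  c(median = m, mad = stats::mad(values, center = m, constant = mad_constant))
}

#' Dichotomise records into high/low reward classes
#'
#' A species is "high" reward when its sugar content strictly exceeds the
#' threshold; species at or below the threshold (including exact ties with
#' a subset median) are "low".
#'
#' @param records data frame with a `sugar_ug` column.
#' @param threshold reward threshold in the units of `sugar_ug`.
#' @return `records` with a `reward_class` factor column (`low`/`high`).
#' @export
dichotomize <- function(records, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  records$reward_class <- factor(ifelse(records$sugar_ug > threshold,
                                        "high", "low"),
                                 levels = c("high", "low"))
  records
}

#' Nested species subsets for the reward analysis
#'
#' Builds the five analysis subsets: the complete sample; SS1, excluding
#' species in the UV colour sector; SS2, additionally excluding Asteraceae
#' (whose sugar is measured from compound heads rather than single
#' flowers); SS3, additionally excluding Orchidaceae (frequent food
#' deception); and the Orchidaceae members of SS1 analysed on their own.
#' Reward thresholds are not set here: each subset is re-dichotomised at
#' its own median downstream.
#'
#' @param records data frame with `family` and `sector` columns.
#' @return named list of data frames:
#'   `complete`, `SS1`, `SS2`, `SS3`, `orchids`.
#' @export
make_subsets <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(list(complete = records, SS1 = records, SS2 = records,
                SS3 = records, orchids = records))
  }
  if (anyNA(records$family) || any(!nzchar(records$family))) {
    warning("records with missing family labels are retained but cannot be ",
            "excluded by family", call. = FALSE)
  }
  ss1 <- records[records$sector != "U", , drop = FALSE]
  ss2 <- ss1[ss1$family != "Asteraceae", , drop = FALSE]
  ss3 <- ss2[ss2$family != "Orchidaceae", , drop = FALSE]
  orch <- ss1[ss1$family == "Orchidaceae", , drop = FALSE]
  list(complete = records, SS1 = ss1, SS2 = ss2, SS3 = ss3, orchids = orch)
}

#' Reward-by-colour contingency table
#'
#' Counts of high and low reward species per colour sector. Sectors with no
#' species (e.g. the UV sector after its single member is excluded) are
#' dropped from the table with a message.
#'
#' @param records data frame with `reward_class` and `sector` columns.
#' @return 2 x K integer matrix, rows `high`/`low`, columns the non-empty
#'   sectors in [hexagon_sectors()] order.
#' @export
contingency_table <- function(records) {
  if (is.null(records$reward_class) || anyNA(records$reward_class)) {
    stop("records must be dichotomised first (reward_class unset)", call. = FALSE)
  }
  sec <- factor(as.character(records$sector), levels = hexagon_sectors())
  tab <- table(records$reward_class, sec)
  empty <- colSums(tab) == 0L
  if (any(empty)) {
    message("dropping empty colour sector(s): ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  m <- matrix(as.integer(tab), nrow = 2L,
              dimnames = list(reward = rownames(tab), sector = colnames(tab)))
  m
}

#' Pearson chi-square statistic
#'
#' Sum of (observed - expected)^2 / expected with expected counts from the
#' product of the table margins. No continuity correction; the statistic is
#' referred to a Monte-Carlo null, not the asymptotic chi-square
#' distribution.
#'
#' @param table matrix of non-negative counts with positive row and column
#'   sums.
#' @return the chi-square statistic.
#' @export
pearson_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has an all-zero margin", call. = FALSE)
  }
  E <- outer(rs, cs) / n
  sum((table - E)^2 / E)
}

#' Monte-Carlo p-value for a contingency table
#'
#' Simulates `n_sim` tables uniformly from the null of independence with
#' both margins fixed (Patefield's algorithm, via [stats::r2dtable()]) and
#' compares their chi-square statistics to the observed one. The p-value
#' uses the add-one estimator (1 + c) / (n_sim + 1), which can never be
#' exactly zero.
#'
#' @param table observed count matrix.
#' @param n_sim number of simulated tables (default 100000).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return object of class `contingency_result`: list with `table`, `chisq`,
#'   `p_mc`, `n_sim`, `seed`.
#' @export
monte_carlo_p <- function(table, n_sim = 100000L, seed = NULL) {
  table <- as.matrix(table)
  n_sim <- as.integer(n_sim)
  if (n_sim < 1L) stop("n_sim must be >= 1", call. = FALSE)
  obs <- pearson_chisq(table)
  rs <- rowSums(table); cs <- colSums(table)
  sims <- with_seed(seed, stats::r2dtable(n_sim, rs, cs))
  sim_stat <- vapply(sims, pearson_chisq, numeric(1))
  p <- (1 + sum(sim_stat >= obs - 1e-12)) / (n_sim + 1)
  structure(list(table = table, chisq = obs, p_mc = p,
                 n_sim = n_sim, seed = seed),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo chi-square test (%d simulations)\n", x$n_sim))
  print(x$table)
  cat(sprintf("X-squared = %.4g, p = %.4g\n", x$chisq, x$p_mc))
  invisible(x)
}

## Exact null distribution of Kendall's S = C - D for untied samples of
## size n: number of permutations with k discordant pairs (inversion-count
## recurrence), used for small-sample p-values.
kendall_inversion_counts <- function(n) {
  counts <- 1
  for (m in 2:n) {
    new <- numeric(length(counts) + m - 1)
    for (i in 0:(m - 1)) {
      idx <- seq_along(counts) + i
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  counts
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two vectors, with a two-sided
#' p-value. For n <= 10 without ties the exact permutation null of the
#' concordance score is used; otherwise the normal approximation with the
#' tie-adjusted variance.
#'
#' @param xs,ys numeric vectors of equal length n >= 2.
#' @return object of class `correlation_result`: list with `n`, `tau`, `p`.
#' @export
kendall_tau <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("unequal lengths", call. = FALSE)
  n <- length(xs)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  if (anyNA(xs) || anyNA(ys)) stop("NA in input", call. = FALSE)
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ## pairwise concordance count; O(n^2), fine at community sample sizes
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1L)) {
    dx <- sign(xs[(i + 1L):n] - xs[i])
    dy <- sign(ys[(i + 1L):n] - ys[i])
    C <- C + sum(dx * dy > 0)
    D <- D + sum(dx * dy < 0)
  }
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(xs)); ty <- as.numeric(table(ys))
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 10L) {
    ## exact: S = n0 - 2 * (number of discordant pairs)
    cnt <- kendall_inversion_counts(n)
    s_all <- n0 - 2 * (seq_along(cnt) - 1)
    p <- sum(cnt[abs(s_all) >= abs(S)]) / sum(cnt)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(n = n, tau = tau, p = min(p, 1)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b: tau = %.3f, n = %d, p = %.3g\n",
              x$tau, x$n, x$p))
  invisible(x)
}

#' Full colour-category / nectar-reward analysis
#'
#' Runs the complete reward analysis over the nested species subsets
#' produced by [make_subsets()]: per-subset median and MAD of sugar
#' content, dichotomisation at the subset's own median, the reward-by-
#' sector contingency table with a Monte-Carlo chi-square test (for SS1,
#' SS2 and SS3; the complete sample retains the single UV species, which is
#' why testing starts at SS1), Kendall correlation between sugar content
#' and chromatic contrast for all five subsets, and per-sector proportions
#' of high-reward species.
#'
#' @param records data frame with columns `species`, `family`, `sugar_ug`,
#'   `contrast`, `sector` (e.g. from [read_records()] or
#'   [make_community()]).
#' @param n_sim Monte-Carlo simulations per contingency test.
#' @param seed integer seed controlling the Monte-Carlo draws.
#' @param mad_constant see [median_mad()].
#' @return object of class `reward_report`: list with one entry per subset
#'   (`n`, `median`, `mad`, `threshold`, `tau`, `sector_counts`,
#'   `prop_high`, and for SS1-SS3 `contingency`).
#' @export
run_reward_analysis <- function(records, n_sim = 100000L, seed = NULL,
                                mad_constant = 1.4826) {
  needed <- c("species", "family", "sugar_ug", "contrast", "sector")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  subsets <- make_subsets(records)
  tested <- c("SS1", "SS2", "SS3")
  out <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    if (nrow(sub) == 0L) return(list(n = 0L))
    mm <- median_mad(sub$sugar_ug, mad_constant)
    sub <- dichotomize(sub, mm[["median"]])
    counts <- table(factor(as.character(sub$sector),
                           levels = hexagon_sectors()))
    high <- table(factor(as.character(sub$sector[sub$reward_class == "high"]),
                         levels = hexagon_sectors()))
    res <- list(n = nrow(sub),
                median = mm[["median"]], mad = mm[["mad"]],
                threshold = mm[["median"]],
                tau = kendall_tau(sub$sugar_ug, sub$contrast),
                sector_counts = counts,
                prop_high = ifelse(counts > 0, high / counts, NA_real_))
    if (nm %in% tested) {
      tab <- suppressMessages(contingency_table(sub))
      res$contingency <- monte_carlo_p(tab, n_sim = n_sim, seed = seed)
    }
    res
  })
  names(out) <- names(subsets)
  structure(list(subsets = out, n_sim = n_sim, seed = seed,
                 mad_constant = mad_constant),
            class = "reward_report")
}

#' @export
print.reward_report <- function(x, ...) {
  cat("Colour-category / nectar-reward analysis\n")
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    if (identical(s$n, 0L)) { cat(sprintf("  %-8s empty\n", nm)); next }
    line <- sprintf("  %-8s n=%2d  median=%7.1f ug  MAD=%7.1f  tau=%+.3f (p=%.3g)",
                    nm, s$n, s$median, s$mad, s$tau$tau, s$tau$p)
    if (!is.null(s$contingency)) {
      line <- paste0(line, sprintf("  X2=%.2f (MC p=%.3g)",
                                   s$contingency$chisq, s$contingency$p_mc))
    }
    cat(line, "\n")
  }
  invisible(x)
}
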