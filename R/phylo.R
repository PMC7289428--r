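#' Read a phylogenetic tree
#'
#' Reads a rooted tree with branch lengths from a newick or nexus file
#' (nexus TRANSLATE blocks are handled). Polytomies are allowed; duplicate
#' tip labels are an error.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the file), `"newick"` or `"nexus"`.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    head1 <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(head1, "#NEXUS")) "nexus" else "newick"
  }
  tree <- switch(format,
                 newick = ape::read.tree(path),
                 nexus = ape::read.nexus(path))
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("could not parse tree file: ", path, call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  tree
}

## species names are matched after trimming whitespace and mapping spaces
## to underscores (the usual newick convention)
normalize_label <- function(x) gsub(" ", "_", trimws(x))

#' Brownian-motion covariance matrix of a tree
#'
#' The phylogenetic variance-covariance matrix C: C[i, j] is the shared
#' root-to-MRCA path length of tips i and j, and C[i, i] the root-to-tip
#' depth. Under Brownian motion a trait on the tree is multivariate normal
#' with covariance sigma^2 C. Polytomies are handled natively.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of C by lambda, leaving the diagonal
#' unchanged. lambda = 1 returns the Brownian covariance; lambda = 0 the
#' star phylogeny (phylogenetic independence).
#'
#' @param C covariance matrix from [phylo_vcv()].
#' @param lambda scalar in [0, lambda_max].
#' @param lambda_max upper bound (default 1).
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda, lambda_max = 1) {
  stop_if_not_scalar_number(lambda, "lambda")
  if (lambda < 0 || lambda > lambda_max) {
    stop(sprintf("lambda must lie in [0, %g]", lambda_max), call. = FALSE)
  }
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Brownian-motion log-likelihood of a trait on a covariance
#'
#' Profile log-likelihood of a continuous trait under the multivariate
#' normal model y ~ N(a 1, sigma^2 C): the root state a is the GLS
#' estimate, sigma^2 its maximum-likelihood value, and the returned
#' log-likelihood is evaluated at both.
#'
#' @param trait named numeric vector, names matching `rownames(C)`.
#' @param C positive-definite covariance (e.g. a lambda-transformed
#'   [phylo_vcv()]).
#' @return list with `loglik`, `sigma2`, `root`.
#' @export
bm_loglik <- function(trait, C) {
  if (!is.null(names(trait))) {
    if (!all(rownames(C) %in% names(trait))) {
      stop("trait values missing for some tips", call. = FALSE)
    }
    trait <- trait[rownames(C)]
  }
  n <- length(trait)
  stopifnot(n == nrow(C))
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is singular", call. = FALSE))
  logdet <- 2 * sum(log(diag(L)))
  ## solve via the Cholesky factor: z = L^-T y has cov sigma^2 I
  z <- backsolve(L, trait, transpose = TRUE)
  o <- backsolve(L, rep(1, n), transpose = TRUE)
  root <- sum(o * z) / sum(o * o)
  r <- z - root * o
  sigma2 <- sum(r^2) / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(loglik = loglik, sigma2 = sigma2, root = root)
}

## profile log-likelihood of lambda for trait/tree, memoising the base vcv
profile_lambda_loglik <- function(trait, C, lambda) {
  bm_loglik(trait, lambda_transform(C, lambda, lambda_max = Inf))$loglik
}

#' Fit Pagel's lambda by maximum likelihood
#'
#' Estimates the phylogenetic signal of a continuous trait: lambda scales
#' the off-diagonal (shared-history) part of the Brownian covariance, and
#' is fitted by bounded one-dimensional optimisation of the profile
#' log-likelihood on [0, lambda_max] (tolerance 1e-8, ties broken toward
#' smaller lambda). Tips without trait values are pruned with a message.
#'
#' @param trait named numeric vector of trait values (names are tip
#'   labels, matched after whitespace/underscore normalisation).
#' @param tree an [ape::phylo] tree.
#' @param lambda_max search upper bound (default 1, the Brownian value).
#' @return object of class `phylo_fit`: list with `lambda`, `sigma2`,
#'   `root`, `loglik`, `loglik0` (lambda = 0), `p_value` (likelihood-ratio
#'   test against lambda = 0), `method`, `n_tips`.
#' @export
fit_lambda <- function(trait, tree, lambda_max = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(trait))) stop("trait must be named by tip label", call. = FALSE)
  names(trait) <- normalize_label(names(trait))
  tree$tip.label <- normalize_label(tree$tip.label)
  keep <- intersect(tree$tip.label, names(trait)[is.finite(trait)])
  if (length(keep) < 4L) {
    stop("need at least 4 tips with trait values", call. = FALSE)
  }
  dropped <- setdiff(tree$tip.label, keep)
  if (length(dropped)) {
    message(length(dropped), " tip(s) without trait values pruned from tree")
    tree <- ape::drop.tip(tree, dropped)
  }
  trait <- trait[tree$tip.label]
  C <- phylo_vcv(tree)

  f <- function(l) profile_lambda_loglik(trait, C, l)
  opt <- stats::optimize(f, interval = c(0, lambda_max),
                         maximum = TRUE, tol = 1e-8)
  ## compare against the boundaries; prefer the smaller lambda on ties
  cand <- c(0, opt$maximum, lambda_max)
  ll <- c(f(0), opt$objective, f(lambda_max))
  best <- which(ll >= max(ll) - 1e-10)[1L]
  lambda_hat <- cand[best]
  fit <- bm_loglik(trait, lambda_transform(C, lambda_hat, lambda_max))
  ll0 <- f(0)
  lr <- max(0, 2 * (fit$loglik - ll0))
  structure(list(lambda = lambda_hat, sigma2 = fit$sigma2, root = fit$root,
                 loglik = fit$loglik, loglik0 = ll0,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 method = "LR", n_tips = length(trait)),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda fit (%d tips): lambda = %.3f, sigma2 = %.4g, root = %.4g\n",
    x$n_tips, x$lambda, x$sigma2, x$root))
  cat(sprintf("  logLik = %.3f (lambda = 0: %.3f), %s p = %.4g\n",
              x$loglik, x$loglik0, x$method, x$p_value))
  invisible(x)
}

#' Significance test for phylogenetic signal
#'
#' Tests lambda > 0 either by the likelihood-ratio test against the
#' star-phylogeny null (chi-square with 1 df; the default, matching common
#' practice) or by an explicit randomisation: trait values are shuffled
#' across tips `n_perm` times and the observed log-likelihood gain of the
#' lambda fit is compared with the permutation distribution, with the
#' add-one p-value estimator.
#'
#' @param trait named trait vector.
#' @param tree an [ape::phylo] tree.
#' @param method `"LR"` or `"permutation"`.
#' @param n_perm number of permutations (permutation method only).
#' @param seed optional seed for the permutations.
#' @param lambda_max search upper bound passed to [fit_lambda()].
#' @return the p-value (scalar).
#' @export
lambda_significance <- function(trait, tree, method = c("LR", "permutation"),
                                n_perm = 999L, seed = NULL, lambda_max = 1) {
  method <- match.arg(method)
  fit <- fit_lambda(trait, tree, lambda_max)
  if (method == "LR") return(fit$p_value)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs_gain <- fit$loglik - fit$loglik0
  gains <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- stats::setNames(sample(trait), names(trait))
      pf <- suppressMessages(fit_lambda(perm, tree, lambda_max))
      pf$loglik - pf$loglik0
    }, numeric(1))
  })
  (1 + sum(gains >= obs_gain - 1e-12)) / (n_perm + 1)
}
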