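# Independent oracles used to cross-check the implementation.

## Kendall tau-b by explicit pair classification:
## tau_b = (C - D) / sqrt((C + D + Ty_only)(C + D + Tx_only)),
## where Tx_only counts pairs tied in x but not y (and vice versa).
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- tx_only <- ty_only <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    if (dx == 0) { tx_only <- tx_only + 1; next }
    if (dy == 0) { ty_only <- ty_only + 1; next }
    if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + ty_only) * (C + D + tx_only))
}

## Brownian covariance by brute-force path walking on the edge matrix.
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) { nodes <- c(nodes, node); node <- parent[node] }
    nodes
  }
  depth <- function(nodes) sum(blen[nodes])
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n)) for (j in i:n) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- C[j, i] <- if (i == j) depth(paths[[i]]) else depth(shared)
  }
  C
}

## Trapezoid-rule quadrature.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

## Pearson chi-square written out longhand for oracle use.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

## A tiny toy visual system on a 3-wavelength grid with receptor
## sensitivities that overlap, for end-to-end hand checks.
toy_grid <- c(400, 500, 600)
toy_receptors <- function() {
  structure(list(
    UV = spectral_function(toy_grid, c(1.0, 0.2, 0.0)),
    B  = spectral_function(toy_grid, c(0.1, 1.0, 0.1)),
    G  = spectral_function(toy_grid, c(0.0, 0.3, 1.0))),
    class = "receptor_set")
}
toy_background <- function() spectral_function(toy_grid, c(0.2, 0.3, 0.4))
toy_illuminant <- function() spectral_function(toy_grid, c(1.0, 0.8, 0.6))

## default synthetic study conditions, small Monte-Carlo size for speed
small_community <- function(seed, n_sim = 2000L) {
  comm <- make_community(community_spec(seed = seed))
  run_reward_analysis(comm$records, n_sim = n_sim, seed = seed)
}
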