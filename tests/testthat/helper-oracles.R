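# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: partition enumeration + direct arithmetic for
# modularity, direct mass-function summation for the hypergeometric tail,
# and a literal step-up implementation for Benjamini-Hochberg.

# all set partitions of n items as a matrix of restricted-growth strings
all_partitions <- function(n) {
  out <- matrix(1L, 1, 1)
  if (n == 1) {
    return(out)
  }
  for (i in 2:n) {
    maxlab <- apply(out, 1, max)
    reps <- maxlab + 1L
    out2 <- out[rep(seq_len(nrow(out)), reps), , drop = FALSE]
    newcol <- unlist(lapply(seq_along(reps), function(r) seq_len(reps[r])))
    out <- cbind(out2, newcol)
  }
  unname(out)
}

# maximum weighted modularity over every partition, by exhaustive search
brute_force_best_modularity <- function(g, gamma = 1) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0) {
    return(0)
  }
  P <- all_partitions(n)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, m)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  W <- sum(w)
  k <- igraph::strength(g)
  intra <- numeric(nrow(P))
  for (e in seq_len(m)) {
    intra <- intra + w[e] * (P[, ends[e, 1]] == P[, ends[e, 2]])
  }
  sumsq <- numeric(nrow(P))
  for (lab in seq_len(n)) {
    sumsq <- sumsq + ((P == lab) %*% k)[, 1]^2
  }
  max(intra / W - gamma * sumsq / (4 * W^2))
}

# upper-tail hypergeometric by direct summation of the mass function
hyper_tail_by_summation <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk) / choose(N, n))
}

# literal Benjamini-Hochberg step-up with monotonicity enforcement
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small labelled random graph for oracle comparisons
random_small_graph <- function(n, p = NULL, weighted = TRUE) {
  p <- p %||% stats::runif(1, 0.3, 0.7)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  if (weighted && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
  }
  g
}

`%||%` <- rlang::`%||%`

# two disjoint triangles over a..f, unit-ish confidences
two_triangles <- function(confidence = 0.9) {
  build_network(
    tibble::tibble(
      geneA = c("a", "b", "c", "d", "e", "f"),
      geneB = c("b", "c", "a", "e", "f", "d"),
      confidence = confidence
    ),
    gene_set = letters[1:6], confidence_min = 0
  )
}
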