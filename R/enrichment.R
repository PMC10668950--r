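#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when drawing `n` genes without replacement
#' from a universe of `N` genes of which `K` are annotated. This is the
#' one-sided overrepresentation (Fisher exact upper-tail) p-value.
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe.
#' @param n Query (drawn) genes.
#' @param N Universe size.
#' @return The upper-tail probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper(0, 5, 10, 50) # 1
hypergeom_upper <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0)) {
    stop_nsnet("hypergeom_upper: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of an overlap
#'
#' The percentage of query genes belonging to a set divided by the percentage
#' of universe genes annotated to that set: `(k/n) / (K/N)`.
#'
#' @inheritParams hypergeom_upper
#' @return Fold enrichment (>= 0); `NA` when `K = 0` (undefined).
#' @export
#' @examples
#' fold_enrichment(5, 50, 10, 1000) # 10
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0)) stop_nsnet("fold_enrichment: n must be positive")
  ifelse(K > 0, (k / n) / (K / N), NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving (a thin wrapper over [stats::p.adjust()] so the filter
#' chain has a single named correction step).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric())
  }
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop_nsnet("bh_adjust: p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Overrepresentation of pathway gene sets in each community
#'
#' For every (community, gene set) pair with non-empty overlap, computes the
#' hypergeometric upper-tail p-value, the fold enrichment and the BH-adjusted
#' p-value; adjustment is applied within each community's family of tested
#' sets (matching per-panel presentation of enrichment results). Rows are
#' sorted by community, then adjusted p.
#'
#' @param partition An `ns_partition` or named membership vector.
#' @param gene_sets Named list of gene symbol vectors (e.g. [read_gmt()]).
#' @param universe Universe of gene symbols. Default: union of all genes in
#'   the annotation collection. Every community gene must be in the universe.
#' @param alpha Significance threshold recorded in the `significant` column
#'   (applied to `p_adj`).
#' @return Tibble (`community`, `set`, `k`, `n`, `K`, `N`, `p`, `fold`,
#'   `p_adj`, `significant`).
#' @export
enrich_communities <- function(partition, gene_sets,
                               universe = NULL, alpha = 0.05) {
  memb <- if (inherits(partition, "ns_partition")) partition$membership else partition
  if (is.null(universe)) {
    universe <- sort(unique(unlist(gene_sets)))
  }
  universe <- unique(universe)
  outside <- setdiff(names(memb), universe)
  if (length(outside) > 0) {
    stop_nsnet("enrich_communities: community gene(s) absent from universe: %s",
               paste(head(outside, 5), collapse = ", "))
  }
  N <- length(universe)
  sets_u <- map(gene_sets, ~ intersect(.x, universe))

  res <- map(sort(unique(memb)), function(cm) {
    genes <- intersect(names(memb)[memb == cm], universe)
    n <- length(genes)
    rows <- imap(sets_u, function(set, nm) {
      k <- length(intersect(genes, set))
      if (k == 0) {
        return(NULL)
      }
      K <- length(set)
      tibble(
        community = cm, set = nm, k = k, n = n, K = K, N = N,
        p = hypergeom_upper(k, K, n, N),
        fold = fold_enrichment(k, n, K, N)
      )
    })
    out <- list_rbind(purrr::compact(rows))
    if (nrow(out) > 0) out$p_adj <- bh_adjust(out$p)
    out
  }) |>
    list_rbind()
  if (nrow(res) == 0) {
    return(tibble(
      community = integer(), set = character(), k = integer(), n = integer(),
      K = integer(), N = integer(), p = numeric(), fold = numeric(),
      p_adj = numeric(), significant = logical()
    ))
  }
  res |>
    mutate(significant = .data$p_adj < alpha) |>
    arrange(.data$community, .data$p_adj, .data$set)
}
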