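#' Simulate a confidence-weighted interaction network with planted communities
#'
#' Draws a planted-partition (stochastic block model) graph over synthetic
#' gene symbols: each unordered gene pair receives an edge independently with
#' probability `p_in` when both genes share a planted community and `p_out`
#' otherwise. Edge confidences mimic interaction-database combined scores:
#' within-community confidences are drawn uniformly from \[0.60, 0.98\],
#' between-community from \[0.15, 0.55\], so within-community edges carry
#' systematically higher weight.
#'
#' @param cfg A [sim_config()].
#' @return A list with
#'   * `edges`: tibble with columns `geneA`, `geneB`, `confidence`
#'     (undirected, deduplicated, `geneA < geneB`, no self-edges);
#'   * `truth`: an `ns_planted_truth` list whose `community_of_gene` is a
#'     named integer vector over all genes (communities `1..k`). Downstream
#'     generators fill in the remaining planted-truth slots.
#' @export
#' @examples
#' sim <- simulate_ppi(sim_config(seed = 1, n_genes = 30, n_communities = 3))
#' head(sim$edges)
simulate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "ns_sim_config"))
  genes <- gene_symbols(cfg$n_genes)
  comm <- sort(rep_len(seq_len(cfg$n_communities), cfg$n_genes))
  names(comm) <- genes

  with_seed(cfg$seed, {
    pairs <- utils::combn(cfg$n_genes, 2)
    same <- comm[pairs[1, ]] == comm[pairs[2, ]]
    p <- ifelse(same, cfg$p_in, cfg$p_out)
    keep <- runif(ncol(pairs)) < p
    a <- pairs[1, keep]
    b <- pairs[2, keep]
    within <- same[keep]
    confidence <- ifelse(within,
      runif(sum(keep), 0.60, 0.98),
      runif(sum(keep), 0.15, 0.55)
    )
    edges <- tibble(
      geneA = genes[a], geneB = genes[b],
      confidence = round(confidence, 3)
    ) |>
      arrange(.data$geneA, .data$geneB)
  })

  truth <- structure(
    list(
      community_of_gene = comm,
      enriched_pathway_of_community = NULL,
      enriched_region_of_community = NULL,
      carrier_cases_by_gene = NULL,
      qualifying = NULL
    ),
    class = "ns_planted_truth"
  )
  list(edges = edges, truth = truth)
}
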