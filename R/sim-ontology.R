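#' Simulate a brain anatomy ontology and gene expression calls
#'
#' Builds a `part_of` anatomy DAG rooted at a single "brain" term with
#' `n_regions` region terms as direct children (a flat two-level ontology,
#' matching the "children of the brain term" selection used for real
#' anatomy ontologies), then draws binary present/absent expression calls per
#' (gene, region). The baseline presence probability is 0.3; for genes of
#' community `c` in that community's planted region the presence odds are
#' multiplied by `region_signal_strength`. Planted regions are assigned to
#' communities without replacement while regions last.
#'
#' @param truth Planted truth from [simulate_ppi()].
#' @param cfg A [sim_config()].
#' @return A list with
#'   * `dag`: tibble of edges (`child`, `parent`), acyclic by construction;
#'   * `calls`: tibble of present calls (`gene`, `term`), region terms only;
#'   * `truth`: updated with `enriched_region_of_community`.
#' @export
simulate_ontology_and_calls <- function(truth, cfg) {
  stopifnot(inherits(cfg, "ns_sim_config"), inherits(truth, "ns_planted_truth"))
  comm <- truth$community_of_gene
  genes <- names(comm)
  regions <- sprintf("R%02d", seq_len(cfg$n_regions))
  dag <- tibble(child = regions, parent = "BRAIN")
  stopifnot(is_acyclic(dag)) # flat construction cannot cycle; assert anyway

  base_p <- 0.3
  with_seed(cfg$seed + 3L, {
    planted_regions <- sample(regions, cfg$n_communities,
      replace = cfg$n_communities > cfg$n_regions
    )
    odds <- base_p / (1 - base_p)
    p_hi <- (odds * cfg$region_signal_strength) /
      (1 + odds * cfg$region_signal_strength)
    grid <- tidyr::expand_grid(gene = genes, term = regions) |>
      mutate(
        comm = comm[.data$gene],
        p = ifelse(.data$term == planted_regions[.data$comm], p_hi, base_p),
        present = runif(n()) < .data$p
      )
    calls <- grid |>
      filter(.data$present) |>
      select("gene", "term") |>
      arrange(.data$gene, .data$term)
  })

  truth$enriched_region_of_community <-
    setNames(planted_regions, seq_len(cfg$n_communities))
  list(dag = dag, calls = calls, truth = truth)
}

# cycle check on a child->parent edge table by iterated leaf removal
is_acyclic <- function(dag) {
  edges <- dag
  repeat {
    if (nrow(edges) == 0) {
      return(TRUE)
    }
    leaves <- setdiff(edges$child, edges$parent)
    prunable <- edges$child %in% leaves
    if (!any(prunable)) {
      return(FALSE)
    }
    edges <- edges[!prunable, , drop = FALSE]
  }
}

#' Read an anatomy ontology edge table
#'
#' @param path TSV with columns `child`, `parent` (`part_of` edges).
#' @return Tibble of edges.
#' @export
read_ontology <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"), comment = "#")
}

#' Read a gene-by-region expression call table
#'
#' @param path TSV with columns `gene`, `term`.
#' @return Tibble of present calls.
#' @export
read_expression_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"), comment = "#")
}
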