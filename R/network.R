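#' Build the weighted interaction network over a gene set
#'
#' Keeps edges whose endpoints are both in `gene_set` and whose confidence is
#' at least `confidence_min`; self-edges and duplicate pairs are collapsed
#' (keeping the maximum confidence). Genes of `gene_set` with no surviving
#' edge are retained as degree-0 nodes, since every qualifying gene belongs
#' to the network regardless of connectivity. Raising `confidence_min` never
#' adds edges.
#'
#' @param edge_table Tibble with columns `geneA`, `geneB`, `confidence`.
#' @param gene_set Character vector of gene symbols to span.
#' @param confidence_min Minimum edge confidence in \[0, 1\]; 0.4 is the
#'   conventional "medium confidence" interaction-score cutoff.
#' @return An undirected [igraph::igraph] with vertex attribute `name` and
#'   edge attribute `weight` (the confidence).
#' @export
build_network <- function(edge_table, gene_set, confidence_min = 0.4) {
  if (!is.numeric(confidence_min) || confidence_min < 0 || confidence_min > 1) {
    stop_nsnet("build_network: confidence_min must lie in [0,1]")
  }
  gene_set <- unique(gene_set)
  conf <- suppressWarnings(as.numeric(edge_table$confidence))
  bad <- is.na(conf) | conf < 0 | conf > 1
  if (any(bad)) {
    inform(sprintf("build_network: rejected %d edge row(s) with invalid confidence", sum(bad)))
  }
  edges <- edge_table |>
    mutate(confidence = conf) |>
    filter(!bad,
           .data$geneA %in% gene_set, .data$geneB %in% gene_set,
           .data$geneA != .data$geneB,
           .data$confidence >= confidence_min) |>
    mutate(
      a = pmin(.data$geneA, .data$geneB),
      b = pmax(.data$geneA, .data$geneB)
    )
  edges <- if (nrow(edges) > 0) {
    summarise(edges, confidence = max(.data$confidence), .by = c("a", "b"))
  } else {
    tibble(a = character(), b = character(), confidence = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges |> rename(weight = "confidence"),
    directed = FALSE,
    vertices = tibble(name = sort(gene_set))
  )
  g
}

#' Summary statistics of a network
#'
#' Node and edge counts, the per-node degree table and the average local
#' clustering coefficient, where nodes of degree < 2 contribute 0 and the
#' average runs over all nodes.
#'
#' @param net An igraph network from [build_network()].
#' @return A list with `n_nodes`, `n_edges`, `degree` (tibble `gene`,
#'   `degree`, `weighted_degree`) and `avg_clustering`.
#' @export
network_summary <- function(net) {
  deg <- igraph::degree(net)
  lc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  lc[deg < 2] <- 0
  list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    degree = tibble(
      gene = igraph::V(net)$name,
      degree = as.integer(deg),
      weighted_degree = igraph::strength(net)
    ) |>
      arrange(desc(.data$degree), .data$gene),
    avg_clustering = mean(lc)
  )
}

#' Connected components of a network
#'
#' Components are labelled deterministically: component 1 contains the
#' lexicographically smallest member symbol, and so on.
#'
#' @param net An igraph network.
#' @return Tibble (`gene`, `component`).
#' @export
network_components <- function(net) {
  comp <- igraph::components(net)
  first_member <- tapply(igraph::V(net)$name, comp$membership, min)
  relabel <- match(names(sort(first_member)), names(first_member))
  new_id <- match(comp$membership, relabel)
  tibble(gene = igraph::V(net)$name, component = as.integer(new_id)) |>
    arrange(.data$component, .data$gene)
}

#' Write a network as GraphML and as a TSV edge list
#'
#' @param net An igraph network.
#' @param graphml Path for the GraphML file (or `NULL` to skip).
#' @param tsv Path for the edge-list TSV (or `NULL` to skip).
#' @return Invisibly, a tibble of the edge list.
#' @export
write_network <- function(net, graphml = NULL, tsv = NULL) {
  el <- igraph::as_data_frame(net, what = "edges") |>
    as_tibble() |>
    rename(geneA = "from", geneB = "to", confidence = "weight")
  if (!is.null(graphml)) igraph::write_graph(net, graphml, format = "graphml")
  if (!is.null(tsv)) readr::write_tsv(el, tsv)
  invisible(el)
}
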