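#' Propagate expression calls up a part_of anatomy DAG
#'
#' True-path propagation: a gene called present in a term is present in every
#' ancestor of that term. Idempotent; calls on unknown terms are an error.
#'
#' @param dag Edge tibble (`child`, `parent`); must be acyclic with every
#'   term reaching a single root.
#' @param calls Tibble of present calls (`gene`, `term`).
#' @return Closed call tibble (`gene`, `term`), deduplicated and sorted.
#' @export
propagate_calls <- function(dag, calls) {
  if (!is_acyclic(dag)) {
    stop_nsnet("propagate_calls: ontology edge table contains a cycle")
  }
  terms <- union(dag$child, dag$parent)
  unknown <- setdiff(unique(calls$term), terms)
  if (length(unknown) > 0) {
    stop_nsnet("propagate_calls: call(s) on unknown term(s): %s",
               paste(head(unknown, 5), collapse = ", "))
  }
  parents_of <- split(dag$parent, dag$child)
  anc <- ancestors_table(parents_of, terms)
  calls |>
    mutate(terms = map(.data$term, ~ c(.x, anc[[.x]]))) |>
    select("gene", "terms") |>
    unnest("terms") |>
    rename(term = "terms") |>
    distinct() |>
    arrange(.data$gene, .data$term)
}

# memoised ancestor sets (term -> all ancestors via part_of)
ancestors_table <- function(parents_of, terms) {
  anc <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) {
      return(anc[[t]])
    }
    ps <- parents_of[[t]]
    res <- if (is.null(ps)) character() else {
      unique(c(ps, unlist(lapply(ps, get_anc))))
    }
    anc[[t]] <- res
    res
  }
  setNames(lapply(terms, get_anc), terms)
}

#' Parent-child decorrelated enrichment test for one ontology term
#'
#' Tests whether `query_genes` are overrepresented among the genes annotated
#' to `term`, conditioned on the term's parents: the sampling universe is the
#' union of genes annotated (after propagation) to the term's parents
#' ("parent-child union"; the intersection variant is available via
#' `variant`). On a flat ontology (all terms children of the root) this
#' reduces exactly to the plain hypergeometric test against the root
#' universe.
#'
#' @param term Term identifier (not the root).
#' @param query_genes Character vector of query gene symbols.
#' @param dag Ontology edge tibble (`child`, `parent`).
#' @param closed_calls Propagated calls from [propagate_calls()].
#' @param variant `"union"` (default) or `"intersection"` of parent
#'   annotation sets as the universe.
#' @return Upper-tail p-value; 1 (with a warning) when no gene is annotated
#'   to the term's parents.
#' @export
parent_child_test <- function(term, query_genes, dag, closed_calls,
                              variant = c("union", "intersection")) {
  variant <- match.arg(variant)
  parents <- dag$parent[dag$child == term]
  if (length(parents) == 0) {
    stop_nsnet("parent_child_test: '%s' has no parent (is it the root?)", term)
  }
  by_term <- split(closed_calls$gene, closed_calls$term)
  parent_sets <- lapply(parents, function(p) unique(by_term[[p]] %||% character()))
  uni <- if (variant == "union") {
    unique(unlist(parent_sets))
  } else {
    Reduce(intersect, parent_sets)
  }
  if (length(uni) == 0) {
    warn(sprintf("parent_child_test: no gene annotated to parents of '%s'; p = 1", term))
    return(1)
  }
  term_genes <- intersect(unique(by_term[[term]] %||% character()), uni)
  query <- intersect(unique(query_genes), uni)
  k <- length(intersect(query, term_genes))
  hypergeom_upper(k, K = length(term_genes), n = length(query), N = length(uni))
}

#' Brain-region expression enrichment of communities
#'
#' For each community, every non-root term of the anatomy DAG is tested with
#' [parent_child_test()] and the p-values are BH-adjusted to Q-values across
#' terms within the community. The result is a region-by-community Q-value
#' matrix; rows (regions) with at least one Q below `q_threshold` are the
#' display rows.
#'
#' @param partition An `ns_partition` or named membership vector.
#' @param dag Ontology edge tibble (`child`, `parent`).
#' @param calls Expression call tibble (`gene`, `term`); propagated
#'   internally.
#' @param variant Parent-child universe variant, see [parent_child_test()].
#' @param q_threshold Display threshold on Q (default 0.05).
#' @return An `ns_region_enrichment` object: list with `q` (matrix, regions x
#'   communities), `long` (tibble `community`, `term`, `p`, `q`),
#'   `significant_terms`, `q_threshold`.
#' @export
region_enrichment <- function(partition, dag, calls,
                              variant = "union", q_threshold = 0.05) {
  memb <- if (inherits(partition, "ns_partition")) partition$membership else partition
  closed <- propagate_calls(dag, calls)
  root <- setdiff(dag$parent, dag$child)
  terms <- sort(setdiff(union(dag$child, dag$parent), root))
  comms <- sort(unique(memb))

  long <- map(comms, function(cm) {
    genes <- names(memb)[memb == cm]
    if (!any(genes %in% closed$gene)) {
      warn(sprintf("region_enrichment: community %s has no expressed gene", cm))
    }
    p <- map_dbl(terms, function(t) {
      suppressWarnings(parent_child_test(t, genes, dag, closed, variant = variant))
    })
    tibble(community = cm, term = terms, p = p, q = bh_adjust(p))
  }) |>
    list_rbind()

  q <- long |>
    select("community", "term", "q") |>
    pivot_wider(names_from = "community", values_from = "q") |>
    tibble::column_to_rownames("term") |>
    as.matrix()
  colnames(q) <- as.character(comms)

  structure(
    list(
      q = q,
      long = long,
      significant_terms = rownames(q)[apply(q < q_threshold, 1, any)],
      q_threshold = q_threshold
    ),
    class = "ns_region_enrichment"
  )
}

#' @export
print.ns_region_enrichment <- function(x, ...) {
  cat(sprintf(
    "<ns_region_enrichment> %d regions x %d communities; %d region(s) with Q < %g\n",
    nrow(x$q), ncol(x$q), length(x$significant_terms), x$q_threshold
  ))
  invisible(x)
}

#' Order communities by similarity of their regional enrichment profiles
#'
#' Average-linkage hierarchical clustering on the Euclidean distance between
#' `-log10(Q)` column profiles. Leaf order is deterministic (ties resolved
#' toward the smaller column label by the stable ordering of [stats::hclust()]
#' on column-ordered input).
#'
#' @param x An `ns_region_enrichment` or a numeric Q matrix (regions x
#'   communities).
#' @return A list with `order` (column labels in leaf order) and `tree` (the
#'   [stats::hclust] object); for a single column, the trivial order and a
#'   `NULL` tree.
#' @export
cluster_communities <- function(x) {
  q <- if (inherits(x, "ns_region_enrichment")) x$q else x
  if (ncol(q) == 1) {
    return(list(order = colnames(q), tree = NULL))
  }
  prof <- t(-log10(q))
  prof <- prof[order(rownames(prof)), , drop = FALSE]
  tree <- hclust(dist(prof, method = "euclidean"), method = "average")
  list(order = rownames(prof)[tree$order], tree = tree)
}
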