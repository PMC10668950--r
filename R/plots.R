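#' Bubble plot of community pathway enrichment
#'
#' One panel per community: tested gene sets on the y axis, fold enrichment
#' as colour and overlap size as bubble size, the standard presentation of
#' community overrepresentation results.
#'
#' @param enrichment Tibble from [enrich_communities()].
#' @param max_sets Sets shown per community (smallest adjusted p first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_sets = 10) {
  df <- enrichment |>
    slice_min(.data$p_adj, n = max_sets, by = "community", with_ties = FALSE) |>
    mutate(set = factor(.data$set, levels = rev(sort(unique(.data$set)))))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adj), y = .data$set,
    size = .data$k, colour = .data$fold
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~community, scales = "free_y") +
    ggplot2::scale_colour_viridis_c(name = "fold enrichment") +
    ggplot2::scale_size_continuous(name = "# genes") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL) +
    ggplot2::theme_bw()
}

#' Heatmap of brain-region enrichment Q-values
#'
#' Regions with at least one Q below the display threshold on the rows,
#' communities on the columns (ordered by [cluster_communities()]), cell
#' colour `-log10(Q)`.
#'
#' @param x An `ns_region_enrichment` from [region_enrichment()].
#' @return A ggplot object.
#' @export
plot_region_heatmap <- function(x) {
  stopifnot(inherits(x, "ns_region_enrichment"))
  keep <- if (length(x$significant_terms) > 0) x$significant_terms else rownames(x$q)
  ord <- cluster_communities(x)$order
  df <- x$long |>
    filter(.data$term %in% keep) |>
    mutate(community = factor(.data$community, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$community, y = .data$term, fill = -log10(.data$q)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ Q)) +
    ggplot2::labs(x = "community", y = "brain region") +
    ggplot2::theme_minimal()
}

#' Plot community sizes and case percentages of a partition
#'
#' @param object An `ns_partition`.
#' @param qv Optional qualifying-variant table; when given, bars are
#'   annotated with the percentage of network cases per community.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ns_partition
#' @export
autoplot.ns_partition <- function(object, qv = NULL, ...) {
  df <- if (is.null(qv)) {
    tidy(object) |> count(.data$community, name = "n_genes")
  } else {
    community_case_stats(object, qv)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$community), y = .data$n_genes
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community", y = "# genes") +
    ggplot2::theme_minimal()
  if (!is.null(qv)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$pct_of_network_cases)),
      vjust = -0.3, size = 3
    )
  }
  p
}
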