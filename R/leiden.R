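#' Configuration for Leiden community detection
#'
#' @param quality Quality function: `"modularity"` (weighted Newman-Girvan,
#'   the default, matching modularity optimisation) or `"cpm"` (constant
#'   Potts model, resolution-limit-free, available for sensitivity runs).
#' @param resolution Resolution gamma > 0 (default 1).
#' @param theta Refinement randomness theta > 0 (default 0.01): refinement
#'   merges a node into a candidate sub-community with probability
#'   proportional to `exp(gain / theta)` among quality-non-degrading moves.
#' @param max_passes Maximum move-refine-aggregate passes (default 50).
#' @param n_restarts Independent seeded runs; the best-quality partition is
#'   kept (default 5). Local moving is greedy, so a handful of restarts
#'   reliably escapes the rare shallow optimum.
#' @param seed Integer seed for the node visit order and refinement draws;
#'   restart `r` uses `seed + 1000 * (r - 1)`.
#' @return A list of class `ns_quality_config`.
#' @export
quality_config <- function(quality = c("modularity", "cpm"),
                           resolution = 1.0,
                           theta = 0.01,
                           max_passes = 50L,
                           n_restarts = 5L,
                           seed = 1L) {
  quality <- match.arg(quality)
  if (resolution <= 0 || theta <= 0 || max_passes < 1 || n_restarts < 1) {
    stop_nsnet("quality_config: need resolution > 0, theta > 0, max_passes >= 1, n_restarts >= 1")
  }
  structure(
    list(quality = quality, resolution = resolution, theta = theta,
         max_passes = as.integer(max_passes),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
    class = "ns_quality_config"
  )
}

## ---- internal weighted-graph representation --------------------------------
## Self-loops carry intra-community weight after aggregation. Conventions:
##   W   total edge weight, each undirected edge once, self-loops once
##   k_i weighted degree = sum of incident edge weights + 2 * self-loop
lgraph_from_igraph <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  m <- igraph::ecount(g)
  w <- igraph::E(g)$weight %||% rep(1, m)
  if (m > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    a <- ends[, 1]
    b <- ends[, 2]
  } else {
    a <- b <- integer()
  }
  lgraph(n, nm, a, b, w, node_size = rep(1L, n))
}

lgraph <- function(n, nm, a, b, w, node_size) {
  is_self <- a == b
  self_w <- numeric(n)
  if (any(is_self)) {
    agg <- rowsum(w[is_self], a[is_self])
    self_w[as.integer(rownames(agg))] <- agg[, 1]
  }
  a2 <- a[!is_self]
  b2 <- b[!is_self]
  w2 <- w[!is_self]
  src <- factor(c(a2, b2), levels = seq_len(n))
  adj_nbr <- split(c(b2, a2), src)
  adj_w <- split(c(w2, w2), src)
  k <- vapply(adj_w, sum, 0) + 2 * self_w
  list(
    n = n, names = nm,
    edges_a = a2, edges_b = b2, edges_w = w2,
    adj_nbr = adj_nbr, adj_w = adj_w,
    self_w = self_w, node_size = node_size,
    k = unname(k), W = sum(w2) + sum(self_w)
  )
}

# quality of a membership vector on an lgraph (same value at any aggregation
# level, since aggregation conserves intra weight and degrees)
lg_quality <- function(lg, memb, gamma, quality) {
  intra <- sum(lg$edges_w[memb[lg$edges_a] == memb[lg$edges_b]]) + sum(lg$self_w)
  s_c <- rowsum(lg$k, memb)[, 1]
  if (quality == "modularity") {
    if (lg$W == 0) {
      return(0)
    }
    intra / lg$W - gamma * sum((s_c / (2 * lg$W))^2)
  } else {
    nsize_c <- rowsum(as.numeric(lg$node_size), memb)[, 1]
    intra - gamma * sum(nsize_c * (nsize_c - 1) / 2)
  }
}

# fast local moving with a work queue; returns list(memb, n_moves)
lg_local_move <- function(lg, memb, gamma, quality) {
  n <- lg$n
  memb <- as.integer(factor(memb)) # contiguous labels in 1..n
  s <- numeric(n) # community weighted degrees, indexed by label
  nsize <- numeric(n)
  tmp <- rowsum(lg$k, memb)
  s[as.integer(rownames(tmp))] <- tmp[, 1]
  tmp <- rowsum(as.numeric(lg$node_size), memb)
  nsize[as.integer(rownames(tmp))] <- tmp[, 1]
  free <- setdiff(seq_len(n), unique(memb)) # empty labels, for isolation moves
  two_w <- 2 * lg$W

  order0 <- sample.int(n)
  queue <- collections_queue(order0)
  in_queue <- rep(TRUE, n)
  n_moves <- 0L

  while (queue$size > 0) {
    v <- queue_pop(queue)
    in_queue[v] <- FALSE
    c0 <- memb[v]
    kv <- lg$k[v]
    nbr <- lg$adj_nbr[[v]]
    wts <- lg$adj_w[[v]]
    # weight from v to each neighbouring community
    if (length(nbr) > 0) {
      kvc <- rowsum(wts, memb[nbr])
      cand <- as.integer(rownames(kvc))
      kvc <- kvc[, 1]
    } else {
      cand <- integer()
      kvc <- numeric()
    }
    # remove v from its community
    s[c0] <- s[c0] - kv
    nsize[c0] <- nsize[c0] - lg$node_size[v]
    if (!c0 %in% cand) {
      cand <- c(cand, c0)
      kvc <- c(kvc, 0)
    }
    # isolation candidate: an empty community (c0 itself if now empty)
    if (nsize[c0] > 0 && length(free) > 0) {
      cand <- c(cand, free[1])
      kvc <- c(kvc, 0)
    }
    score <- if (quality == "modularity") {
      if (lg$W == 0) rep(0, length(cand)) else kvc - gamma * kv * s[cand] / two_w
    } else {
      kvc - gamma * lg$node_size[v] * nsize[cand]
    }
    stay <- score[match(c0, cand)]
    best_idx <- which(score > stay + 1e-12)
    if (length(best_idx) > 0) {
      top <- best_idx[score[best_idx] >= max(score[best_idx]) - 1e-12]
      target <- min(cand[top]) # ties in gain -> smallest community label
      memb[v] <- target
      n_moves <- n_moves + 1L
      if (length(free) > 0 && target == free[1]) free <- free[-1]
      if (nsize[c0] == 0 && lg$node_size[v] > 0 && target != c0) free <- c(c0, free)
      wake <- nbr[memb[nbr] != target & !in_queue[nbr]]
      for (u in wake) {
        queue_push(queue, u)
        in_queue[u] <- TRUE
      }
    }
    s[memb[v]] <- s[memb[v]] + kv
    nsize[memb[v]] <- nsize[memb[v]] + lg$node_size[v]
  }
  list(memb = memb, n_moves = n_moves)
}

# minimal amortised FIFO queue (environment-based)
collections_queue <- function(init = integer()) {
  e <- new.env(parent = emptyenv())
  e$buf <- as.integer(init)
  e$head <- 1L
  e$size <- length(init)
  e
}
queue_push <- function(e, x) {
  e$buf <- c(e$buf, as.integer(x))
  e$size <- e$size + 1L
  invisible(e)
}
queue_pop <- function(e) {
  x <- e$buf[e$head]
  e$head <- e$head + 1L
  e$size <- e$size - 1L
  if (e$head > 1024L && e$head > length(e$buf) / 2) {
    e$buf <- e$buf[e$head:length(e$buf)]
    e$head <- 1L
  }
  x
}

# refinement: within each community of memb, re-cluster from singletons by
# randomised non-degrading merges (probability ~ exp(gain / theta))
lg_refine <- function(lg, memb, gamma, quality, theta) {
  n <- lg$n
  ref <- seq_len(n) # refined membership, starts as singletons
  sref <- lg$k
  nsref <- as.numeric(lg$node_size)
  two_w <- 2 * lg$W
  singleton <- rep(TRUE, n)

  for (v in sample.int(n)) {
    if (!singleton[v]) next
    nbr <- lg$adj_nbr[[v]]
    wts <- lg$adj_w[[v]]
    same <- memb[nbr] == memb[v]
    if (!any(same)) next
    kvc <- rowsum(wts[same], ref[nbr[same]])
    cand <- as.integer(rownames(kvc))
    kvc <- kvc[, 1]
    cand_keep <- cand != ref[v]
    cand <- cand[cand_keep]
    kvc <- kvc[cand_keep]
    if (length(cand) == 0) next
    kv <- lg$k[v]
    gain <- if (quality == "modularity") {
      if (lg$W == 0) rep(0, length(cand)) else (kvc - gamma * kv * sref[cand] / two_w) / lg$W
    } else {
      kvc - gamma * lg$node_size[v] * nsref[cand]
    }
    ok <- gain >= -1e-12
    if (!any(ok)) next
    cand <- cand[ok]
    gain <- gain[ok]
    # stay-singleton option has gain 0
    pr <- exp(pmin(c(0, gain) / theta, 700))
    pick <- sample.int(length(pr), 1, prob = pr)
    if (pick == 1L) next
    d <- cand[pick - 1L]
    sref[d] <- sref[d] + kv
    nsref[d] <- nsref[d] + lg$node_size[v]
    ref[v] <- d
    singleton[v] <- FALSE
    singleton[d] <- FALSE
  }
  ref
}

# aggregate lg by refined membership; returns new lgraph + old-node -> new-node map
lg_aggregate <- function(lg, ref) {
  labels <- sort(unique(ref))
  map <- match(ref, labels)
  n_new <- length(labels)
  a <- map[lg$edges_a]
  b <- map[lg$edges_b]
  key <- paste(pmin(a, b), pmax(a, b))
  agg_w <- rowsum(lg$edges_w, key)
  ab <- do.call(rbind, strsplit(rownames(agg_w), " ", fixed = TRUE))
  self_extra <- rowsum(lg$self_w, map)
  self_idx <- as.integer(rownames(self_extra))
  a2 <- as.integer(ab[, 1])
  b2 <- as.integer(ab[, 2])
  w2 <- agg_w[, 1]
  keep <- self_extra[, 1] > 0
  a_all <- c(a2, self_idx[keep])
  b_all <- c(b2, self_idx[keep])
  w_all <- c(w2, self_extra[keep, 1])
  size_new <- rowsum(as.numeric(lg$node_size), map)[, 1]
  new_lg <- lgraph(n_new, as.character(seq_len(n_new)), a_all, b_all, w_all,
                   node_size = as.integer(size_new))
  list(lg = new_lg, map = map)
}

#' One refinement + aggregation step of the Leiden algorithm
#'
#' Exposed for inspection and testing of the algorithm's inner phases: given
#' a partition, refine each community into well-connected sub-communities
#' (randomised non-degrading merges starting from singletons) and aggregate
#' the graph by the refined partition. Aggregation conserves total edge
#' weight: intra-community weight becomes self-loop weight.
#'
#' @param net An igraph network.
#' @param membership Integer community labels aligned with `igraph::V(net)`
#'   (or named by vertex name).
#' @param cfg A [quality_config()].
#' @return A list with `aggregated` (igraph, with self-loops and `weight`
#'   edge attribute), `refined` (refined membership for the input nodes) and
#'   `aggregate_membership` (community of each aggregated node).
#' @export
refine_and_aggregate <- function(net, membership, cfg = quality_config()) {
  lg <- lgraph_from_igraph(net)
  memb <- align_membership(net, membership)
  with_seed(cfg$seed, {
    ref <- lg_refine(lg, memb, cfg$resolution, cfg$quality, cfg$theta)
    agg <- lg_aggregate(lg, ref)
  })
  agg_memb <- memb[match(seq_len(agg$lg$n), agg$map)]
  g2 <- igraph::graph_from_data_frame(
    data.frame(
      from = c(agg$lg$edges_a, which(agg$lg$self_w > 0)),
      to = c(agg$lg$edges_b, which(agg$lg$self_w > 0)),
      weight = c(agg$lg$edges_w, agg$lg$self_w[agg$lg$self_w > 0])
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(agg$lg$n)))
  )
  list(aggregated = g2, refined = agg$map, aggregate_membership = agg_memb)
}

align_membership <- function(net, membership) {
  nm <- igraph::V(net)$name
  if (!is.null(names(membership))) {
    missing <- setdiff(nm, names(membership))
    if (length(missing) > 0) {
      stop_nsnet("membership does not cover node(s): %s",
                 paste(head(missing, 5), collapse = ", "))
    }
    membership <- membership[nm]
  } else if (length(membership) != length(nm)) {
    stop_nsnet("membership length %d does not match node count %d",
               length(membership), length(nm))
  }
  m <- as.integer(as.factor(membership))
  if (anyNA(m)) stop_nsnet("membership contains NA labels")
  m
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c ( w_c / W - gamma * (s_c / 2W)^2 )` with `W` the total edge
#' weight, `w_c` the intra-community weight and `s_c` the community's summed
#' weighted degree. For an edgeless network `Q` is defined as 0.
#'
#' @param net An igraph network (edge attribute `weight`, defaulting to 1).
#' @param membership Community labels aligned with `igraph::V(net)` or named
#'   by vertex name; must cover every node.
#' @param gamma Resolution (default 1; `Q` lies in \[-1, 1\] at `gamma = 1`).
#' @return The modularity score.
#' @export
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' partition_modularity(g, c(a = 1, b = 1, c = 1)) # 0
partition_modularity <- function(net, membership, gamma = 1) {
  lg <- lgraph_from_igraph(net)
  memb <- align_membership(net, membership)
  lg_quality(lg, memb, gamma, "modularity")
}

#' Constant Potts model score of a partition
#'
#' `H = sum_c ( w_c - gamma * n_c (n_c - 1) / 2 )` with `n_c` community node
#' counts.
#'
#' @inheritParams partition_modularity
#' @return The CPM score.
#' @export
partition_cpm <- function(net, membership, gamma = 1) {
  lg <- lgraph_from_igraph(net)
  memb <- align_membership(net, membership)
  lg_quality(lg, memb, gamma, "cpm")
}

#' Leiden community detection
#'
#' From-scratch implementation of the Leiden algorithm: iterated (1) local
#' moving of nodes with a work queue that revisits neighbours of moved nodes,
#' (2) randomised refinement of each community from singletons, and (3)
#' aggregation of the graph by the refined partition, until a pass makes no
#' move or `max_passes` is reached. Quality never decreases between passes,
#' the result is deterministic given `cfg$seed`, and every community induces
#' a connected subgraph (degree-0 nodes form singleton communities). The
#' number of communities is an output of the optimisation, never a
#' parameter.
#'
#' @param net An igraph network, e.g. from [build_network()]; edge attribute
#'   `weight` is used when present (unweighted mode = all weights 1).
#' @param cfg A [quality_config()].
#' @return An object of class `ns_partition`: list with `membership` (named
#'   integer vector, labels contiguous `0..k-1`, ordered by decreasing
#'   community size then smallest member symbol), `quality`, `n_communities`,
#'   `passes`, `quality_trace` and `cfg`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' g <- build_network(
#'   tibble::tibble(
#'     geneA = c("a", "b", "c", "d", "e", "f"),
#'     geneB = c("b", "c", "a", "e", "f", "d"),
#'     confidence = 0.9
#'   ),
#'   gene_set = letters[1:6], confidence_min = 0
#' )
#' leiden_communities(g)$n_communities # two triangles -> 2
leiden_communities <- function(net, cfg = quality_config()) {
  stopifnot(inherits(cfg, "ns_quality_config"))
  if (igraph::vcount(net) == 0) {
    stop_nsnet("leiden_communities: empty network")
  }
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  lg0 <- lgraph_from_igraph(net)

  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    run <- leiden_once(lg0, cfg, cfg$seed + 1000L * (r - 1L), random_init = r > 1L)
    if (is.null(best) || run$quality > best$quality + 1e-12) best <- run
  }
  final <- best$final
  passes <- best$passes
  trace <- best$trace

  # safety: communities must induce connected subgraphs; splitting a
  # disconnected community can only increase modularity (s_c^2 is convex)
  final <- split_disconnected(lg0, final)

  membership <- canonical_labels(final, nm)
  q <- lg_quality(lg0, final, cfg$resolution, cfg$quality)
  structure(
    list(
      membership = membership,
      quality = q,
      n_communities = length(unique(membership)),
      passes = passes,
      quality_trace = trace,
      cfg = cfg
    ),
    class = "ns_partition"
  )
}

# one full Leiden run (move-refine-aggregate passes); the first restart
# starts from singletons, later ones from a random coarse partition so the
# greedy local moving explores different basins
leiden_once <- function(lg0, cfg, seed, random_init = FALSE) {
  with_seed(seed, {
    lg <- lg0
    leaf <- seq_len(lg$n) # original node -> current aggregate node
    memb <- if (random_init && lg$n > 2) {
      sample.int(max(2L, ceiling(lg$n / 3)), lg$n, replace = TRUE)
    } else {
      seq_len(lg$n)
    }
    trace <- numeric()
    passes <- 0L
    repeat {
      passes <- passes + 1L
      mv <- lg_local_move(lg, memb, cfg$resolution, cfg$quality)
      memb <- mv$memb
      trace <- c(trace, lg_quality(lg, memb, cfg$resolution, cfg$quality))
      if (mv$n_moves == 0L && passes > 1L) break
      ref <- lg_refine(lg, memb, cfg$resolution, cfg$quality, cfg$theta)
      agg <- lg_aggregate(lg, ref)
      if (agg$lg$n == lg$n) { # refinement kept all singletons: fixed point
        if (mv$n_moves == 0L) break
        if (passes >= cfg$max_passes) break
        next
      }
      memb <- memb[match(seq_len(agg$lg$n), agg$map)]
      leaf <- agg$map[leaf]
      lg <- agg$lg
      if (passes >= cfg$max_passes) break
    }
    final <- memb[leaf]
  })
  list(
    final = final, passes = passes, trace = trace,
    quality = lg_quality(lg0, final, cfg$resolution, cfg$quality)
  )
}

split_disconnected <- function(lg, memb) {
  # label each node by (community, component-within-community)
  out <- memb
  next_label <- max(memb) + 1L
  for (c in unique(memb)) {
    nodes <- which(memb == c)
    if (length(nodes) <= 1) next
    # BFS over induced subgraph
    comp <- rep(0L, lg$n)
    cid <- 0L
    for (start in nodes) {
      if (comp[start] != 0L) next
      cid <- cid + 1L
      frontier <- start
      comp[start] <- cid
      while (length(frontier) > 0) {
        nxt <- unlist(lapply(frontier, function(v) {
          nb <- lg$adj_nbr[[v]]
          nb[memb[nb] == c & comp[nb] == 0L]
        }))
        nxt <- unique(nxt)
        comp[nxt] <- cid
        frontier <- nxt
      }
    }
    if (cid > 1L) {
      for (i in 2:cid) {
        out[nodes[comp[nodes] == i]] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  out
}

# contiguous 0-based labels ordered by decreasing size, ties by smallest member
canonical_labels <- function(memb, nm) {
  sizes <- table(memb)
  first <- tapply(nm, memb, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  old <- names(sizes)[ord]
  new <- setNames(seq_along(old) - 1L, old)
  setNames(as.integer(new[as.character(memb)]), nm)
}

#' @export
print.ns_partition <- function(x, ...) {
  cat(sprintf(
    "<ns_partition> %d nodes, %d communities, %s = %.4f (gamma = %g, %d passes)\n",
    length(x$membership), x$n_communities, x$cfg$quality, x$quality,
    x$cfg$resolution, x$passes
  ))
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat("community sizes:", paste(as.vector(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Leiden partition into a gene-community tibble
#'
#' @param x An `ns_partition`.
#' @param ... Unused.
#' @return Tibble (`gene`, `community`).
#' @method tidy ns_partition
#' @export
tidy.ns_partition <- function(x, ...) {
  tibble(gene = names(x$membership), community = as.integer(x$membership)) |>
    arrange(.data$community, .data$gene)
}

#' One-row summary of a Leiden partition
#'
#' @param x An `ns_partition`.
#' @param ... Unused.
#' @return One-row tibble (`n_nodes`, `n_communities`, `quality`, `passes`,
#'   `resolution`, `quality_fn`).
#' @method glance ns_partition
#' @export
glance.ns_partition <- function(x, ...) {
  tibble(
    n_nodes = length(x$membership),
    n_communities = x$n_communities,
    quality = x$quality,
    passes = x$passes,
    resolution = x$cfg$resolution,
    quality_fn = x$cfg$quality
  )
}

#' Per-community gene, variant and case statistics
#'
#' A case counts toward every community containing at least one gene in which
#' it carries a qualifying variant (so cases may count in several
#' communities); the percentage denominator is the number of distinct cases
#' across the whole network.
#'
#' @param partition An `ns_partition` (or named membership vector).
#' @param qv Qualifying-variant tibble; every `qv` gene must be a partition
#'   node.
#' @return Tibble (`community`, `n_genes`, `n_variants`, `n_cases`,
#'   `pct_of_network_cases` — rounded half-away-from-zero to one decimal).
#' @export
community_case_stats <- function(partition, qv) {
  memb <- if (inherits(partition, "ns_partition")) partition$membership else partition
  missing <- setdiff(unique(qv$gene), names(memb))
  if (length(missing) > 0) {
    stop_nsnet("community_case_stats: gene(s) absent from partition: %s",
               paste(head(missing, 5), collapse = ", "))
  }
  network_cases <- unique(unlist(qv$carriers))
  per_gene <- tibble(gene = names(memb), community = as.integer(memb))
  var_stats <- qv |>
    as_tibble() |>
    mutate(community = memb[.data$gene]) |>
    summarise(
      n_variants = n(),
      n_cases = length(unique(unlist(.data$carriers))),
      .by = "community"
    )
  per_gene |>
    count(.data$community, name = "n_genes") |>
    left_join(var_stats, by = "community") |>
    mutate(
      n_variants = coalesce(.data$n_variants, 0L),
      n_cases = coalesce(.data$n_cases, 0L),
      pct_of_network_cases = round_half_away(
        100 * .data$n_cases / max(1L, length(network_cases)), 1
      )
    ) |>
    arrange(.data$community)
}
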