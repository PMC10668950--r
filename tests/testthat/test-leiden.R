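test_that("modularity matches closed-form values on small graphs", {
  tri <- build_network(
    tibble::tibble(geneA = c("a", "b", "c"), geneB = c("b", "c", "a"),
                   confidence = 1),
    letters[1:3], 0
  )
  # one community: w_c/W = 1 and (s_c/2W)^2 = 1 cancel
  expect_equal(partition_modularity(tri, c(a = 1, b = 1, c = 1)), 0)
  # unweighted triangle, all singletons: 0 - 3 * (2/6)^2 = -1/3
  expect_equal(partition_modularity(tri, c(a = 1, b = 2, c = 3)), -1 / 3)
  expect_error(partition_modularity(tri, c(a = 1, b = 2)), "cover")
})

test_that("modularity agrees with the igraph implementation on random graphs", {
  set.seed(31)
  for (i in 1:20) {
    g <- random_small_graph(sample(5:10, 1))
    memb <- sample(1:3, igraph::vcount(g), replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(
      partition_modularity(g, memb),
      igraph::modularity(g, memb, weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("the natural 2-split of two bridged triangles is the brute-force optimum", {
  et <- tibble::tibble(
    geneA = c("a", "b", "c", "d", "e", "f", "c"),
    geneB = c("b", "c", "a", "e", "f", "d", "d"),
    confidence = 1
  )
  g <- build_network(et, letters[1:6], 0)
  split2 <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  q_split <- partition_modularity(g, split2)
  expect_equal(q_split, brute_force_best_modularity(g), tolerance = 1e-12)
  found <- leiden_communities(g)
  expect_equal(found$quality, q_split, tolerance = 1e-12)
  expect_equal(found$n_communities, 2)
})

test_that("two disjoint triangles resolve into exactly their components", {
  p <- leiden_communities(two_triangles())
  expect_equal(p$n_communities, 2)
  expect_equal(unname(p$membership[c("a", "b", "c")]), rep(p$membership[["a"]], 3))
  expect_equal(unname(p$membership[c("d", "e", "f")]), rep(p$membership[["d"]], 3))
  expect_true(all(sort(unique(p$membership)) == 0:1)) # contiguous 0-based labels
})

test_that("an edgeless network yields all singleton communities", {
  lone <- build_network(tibble::tibble(
    geneA = character(), geneB = character(), confidence = numeric()
  ), letters[1:5], 0)
  p <- leiden_communities(lone)
  expect_equal(p$n_communities, 5)
  expect_equal(p$quality, 0)
})

test_that("leiden matches the brute-force modularity optimum on small graphs", {
  set.seed(99)
  nmatch <- 0
  total <- 30 # the full 100-graph comparison runs in the acceptance suite
  for (i in seq_len(total)) {
    g <- random_small_graph(sample(5:8, 1))
    best <- brute_force_best_modularity(g)
    found <- leiden_communities(g, quality_config(seed = i))$quality
    expect_lte(found, best + 1e-9) # never exceeds the true optimum
    if (found >= best - 1e-9) nmatch <- nmatch + 1
  }
  expect_gte(nmatch / total, 0.95)
})

test_that("quality is monotone over passes and deterministic given a seed", {
  sim <- simulate_ppi(sim_config(seed = 21, n_genes = 60, n_communities = 3))
  net <- build_network(sim$edges, names(sim$truth$community_of_gene), 0)
  p1 <- leiden_communities(net, quality_config(seed = 5))
  p2 <- leiden_communities(net, quality_config(seed = 5))
  expect_identical(p1$membership, p2$membership)
  expect_true(all(diff(p1$quality_trace) >= -1e-12))
  # a Partition covers every node exactly once with contiguous labels
  expect_setequal(names(p1$membership), igraph::V(net)$name)
  expect_equal(sort(unique(unname(p1$membership))),
               0:(p1$n_communities - 1))
})

test_that("communities induce connected subgraphs", {
  set.seed(55)
  for (i in 1:5) {
    g <- random_small_graph(15, p = 0.2)
    p <- leiden_communities(g, quality_config(seed = i))
    for (cm in unique(p$membership)) {
      nodes <- names(p$membership)[p$membership == cm]
      sub <- igraph::induced_subgraph(g, nodes)
      expect_true(igraph::is_connected(sub) || length(nodes) == 1)
    }
  }
})

test_that("relabelling nodes leaves the partition structure unchanged", {
  sim <- simulate_ppi(sim_config(seed = 33, n_genes = 40, n_communities = 4))
  et <- sim$edges
  genes <- names(sim$truth$community_of_gene)
  p1 <- leiden_communities(build_network(et, genes, 0), quality_config(seed = 2))
  # permute the gene symbols
  perm <- setNames(sample(genes), genes)
  et2 <- tibble::tibble(
    geneA = unname(perm[et$geneA]), geneB = unname(perm[et$geneB]),
    confidence = et$confidence
  )
  p2 <- leiden_communities(build_network(et2, unname(perm), 0),
                           quality_config(seed = 2))
  # same structure: NMI of the permuted-back memberships is 1
  expect_equal(nmi(p1$membership[genes], p2$membership[unname(perm[genes])]), 1)
  expect_equal(p1$quality, p2$quality, tolerance = 1e-9)
})

test_that("refine_and_aggregate conserves weight and respects the partition", {
  g <- two_triangles()
  memb <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  out <- refine_and_aggregate(g, memb, quality_config(seed = 1))
  w_in <- sum(igraph::E(g)$weight)
  w_out <- sum(igraph::E(out$aggregated)$weight)
  expect_equal(w_in, w_out) # intra weight moves onto self-loops
  expect_lte(igraph::vcount(out$aggregated), 6)
  # refined communities never straddle the input partition
  expect_true(all(tapply(memb, out$refined, function(x) length(unique(x))) == 1))
  # all-singleton partition: aggregate has one node per input node
  singletons <- setNames(1:6, letters[1:6])
  out2 <- refine_and_aggregate(g, singletons, quality_config(seed = 1))
  expect_equal(igraph::vcount(out2$aggregated), 6)
  expect_equal(sum(igraph::E(out2$aggregated)$weight), w_in)
})

test_that("cpm quality is available and counts node pairs", {
  g <- two_triangles(confidence = 1)
  one <- setNames(rep(1, 6), letters[1:6])
  # single community: 6 intra edges - gamma * 15 pairs
  expect_equal(partition_cpm(g, one, gamma = 1), 6 - 15)
  split2 <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(partition_cpm(g, split2, gamma = 1), 6 - 6)
  p <- leiden_communities(g, quality_config(quality = "cpm", resolution = 0.5))
  expect_equal(p$n_communities, 2)
})

test_that("community case stats count cases in every community they touch", {
  net <- two_triangles()
  p <- leiden_communities(net)
  qv <- dplyr::bind_rows(
    qv_row("1:1:A:T", "a", c("S1", "S2")),
    qv_row("1:2:A:T", "b", "S1"),
    qv_row("1:3:A:T", "d", c("S1", "S3"))
  )
  st <- community_case_stats(p, qv)
  expect_equal(sum(st$n_genes), 6)
  ca <- st$n_cases[st$community == p$membership[["a"]]]
  cd <- st$n_cases[st$community == p$membership[["d"]]]
  expect_equal(ca, 2) # S1, S2
  expect_equal(cd, 2) # S1 counted here too, plus S3
  expect_equal(st$pct_of_network_cases[st$community == p$membership[["a"]]],
               round(100 * 2 / 3, 1))
  expect_error(community_case_stats(p, qv_row("1:9:A:T", "zz", "S9")), "zz")
  # single-community network holds 100% of network cases
  tri <- build_network(
    tibble::tibble(geneA = c("a", "b", "c"), geneB = c("b", "c", "a"),
                   confidence = 1),
    letters[1:3], 0
  )
  st1 <- community_case_stats(leiden_communities(tri),
                              qv_row("1:1:A:T", "a", c("S1", "S2")))
  expect_equal(st1$pct_of_network_cases, 100)
})

test_that("tidy and glance expose the partition as tibbles", {
  p <- leiden_communities(two_triangles())
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene", "community"))
  expect_equal(nrow(td), 6)
  gl <- glance(p)
  expect_equal(gl$n_communities, 2)
  expect_equal(gl$quality_fn, "modularity")
  expect_s3_class(autoplot(p), "ggplot")
})
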