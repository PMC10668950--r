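test_that("sim_config validates probabilities and counts", {
  expect_s3_class(sim_config(seed = 1), "ns_sim_config")
  expect_error(sim_config(p_in = 1.2), "probabilities")
  expect_error(sim_config(lof_rate_per_gene = -0.1), "probabilities")
  expect_error(sim_config(n_genes = 2, n_communities = 3), "n_genes")
  expect_error(sim_config(n_regions = 1), "n_regions")
})

test_that("deterministic planted-partition limits hold", {
  # p_in = 1, p_out = 0: two disjoint cliques of 3
  cfg <- sim_config(seed = 1, n_genes = 6, n_communities = 2, p_in = 1, p_out = 0)
  sim <- simulate_ppi(cfg)
  expect_equal(nrow(sim$edges), 2 * choose(3, 2))
  comm <- sim$truth$community_of_gene
  expect_true(all(comm[sim$edges$geneA] == comm[sim$edges$geneB]))
  # p_in = p_out = 0: empty edge table
  cfg0 <- sim_config(seed = 1, n_genes = 6, n_communities = 2, p_in = 0, p_out = 0)
  expect_equal(nrow(simulate_ppi(cfg0)$edges), 0)
})

test_that("realized edge counts stay within 3 SD of binomial expectation", {
  cfg <- sim_config(seed = 1, n_genes = 60, n_communities = 3,
                    p_in = 0.3, p_out = 0.02)
  sim <- simulate_ppi(cfg)
  comm <- sim$truth$community_of_gene
  within <- sum(comm[sim$edges$geneA] == comm[sim$edges$geneB])
  between <- nrow(sim$edges) - within
  n_within_pairs <- 3 * choose(20, 2) # three blocks of 20
  n_between_pairs <- choose(60, 2) - n_within_pairs
  for (obs_np in list(c(within, n_within_pairs, 0.3),
                      c(between, n_between_pairs, 0.02))) {
    mu <- obs_np[2] * obs_np[3]
    sd <- sqrt(obs_np[2] * obs_np[3] * (1 - obs_np[3]))
    expect_lt(abs(obs_np[1] - mu), 3 * sd)
  }
  # within-community confidences drawn higher than between
  w_conf <- sim$edges$confidence[comm[sim$edges$geneA] == comm[sim$edges$geneB]]
  b_conf <- sim$edges$confidence[comm[sim$edges$geneA] != comm[sim$edges$geneB]]
  expect_gt(mean(w_conf), mean(b_conf))
})

test_that("simulated edge tables are undirected, deduplicated, self-edge free", {
  sim <- simulate_ppi(sim_config(seed = 3, n_genes = 40, n_communities = 4))
  expect_true(all(sim$edges$geneA < sim$edges$geneB))
  expect_false(any(duplicated(sim$edges[, c("geneA", "geneB")])))
  expect_true(all(sim$edges$confidence >= 0 & sim$edges$confidence <= 1))
})

test_that("zero LoF rate plants zero qualifying sites", {
  cfg <- sim_config(seed = 2, n_genes = 20, n_communities = 2, n_cases = 30,
                    lof_rate_per_gene = 0)
  sim <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, sim$truth)
  expect_equal(nrow(cohort$truth$qualifying), 0)
  expect_equal(sum(cohort$sites$planted == "qualifying"), 0)
})

test_that("the filter chain recovers exactly the planted qualifying set", {
  for (seed in c(7, 11, 23)) {
    cfg <- sim_config(seed = seed, n_genes = 40, n_communities = 4, n_cases = 80)
    sim <- simulate_ppi(cfg)
    cohort <- simulate_cohort(cfg, sim$truth)
    qv <- qualifying_variants(cohort, cohort$control_af,
                              names(sim$truth$community_of_gene))
    expect_setequal(qv$key, cohort$truth$qualifying$key)
  }
})

test_that("every contaminant site fails exactly its planted filter", {
  cfg <- sim_config(seed = 5, n_genes = 40, n_communities = 4, n_cases = 80)
  sim <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, sim$truth)
  th <- qc_thresholds()
  qc <- apply_qc(cohort, th)
  sites <- dplyr::left_join(qc$sites,
                            dplyr::select(cohort$sites, "key", planted2 = "planted"),
                            by = "key")

  vq_ok <- !is.na(sites$vqslod) & sites$vqslod >= th$vqslod_min
  miss_ok <- sites$missingness < th$missingness_max
  geno_ok <- sites$n_passing_carriers > 0
  af <- cohort$control_af$af[match(sites$key, cohort$control_af$key)]
  freq_ok <- is.na(af) | pmin(af, 1 - af) < th$maf_max
  lof_ok <- sites$consequence %in% lof_classes()
  cand_ok <- sites$gene %in% names(sim$truth$community_of_gene)

  checks <- data.frame(
    vq = vq_ok, miss = miss_ok, geno = geno_ok,
    freq = freq_ok, lof = lof_ok, cand = cand_ok
  )
  fail_of <- c(
    fail_vqslod = "vq", fail_missingness = "miss", fail_dp = "geno",
    fail_gq = "geno", fail_ab = "geno", fail_frequency = "freq",
    fail_lof = "lof", fail_candidate = "cand"
  )
  for (i in seq_len(nrow(sites))) {
    kind <- sites$planted2[i]
    if (kind == "qualifying") {
      expect_true(all(unlist(checks[i, ])), label = sprintf("site %s clean", sites$key[i]))
    } else {
      expected_fail <- fail_of[[kind]]
      expect_false(checks[i, expected_fail],
                   label = sprintf("site %s fails %s", sites$key[i], kind))
      expect_true(all(unlist(checks[i, setdiff(names(checks), expected_fail)])),
                  label = sprintf("site %s passes all other filters", sites$key[i]))
    }
  }
})

test_that("planted common sites always fall to the frequency filter", {
  cfg <- sim_config(seed = 9, n_genes = 30, n_communities = 3, n_cases = 50)
  sim <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, sim$truth)
  common <- cohort$sites[cohort$sites$planted == "fail_frequency", ]
  expect_gt(nrow(common), 0)
  kept <- filter_population_frequency(common, cohort$control_af, 0.001)
  expect_equal(nrow(kept), 0)
})

test_that("planted pathway sets respect purity", {
  cfg <- sim_config(seed = 4, n_genes = 50, n_communities = 5, pathway_purity = 1)
  sim <- simulate_ppi(cfg)
  ann <- simulate_annotations(sim$truth, cfg)
  comm <- sim$truth$community_of_gene
  for (cm in seq_len(cfg$n_communities)) {
    set_name <- ann$truth$enriched_pathway_of_community[[as.character(cm)]]
    members <- ann$gene_sets[[set_name]]
    expect_true(all(comm[members] == cm), label = sprintf("community %d pure set", cm))
  }
  expect_length(ann$gene_sets, cfg$n_pathways)
})

test_that("simulated ontology is an acyclic part_of tree with planted calls", {
  cfg <- sim_config(seed = 6, n_genes = 30, n_communities = 3, n_regions = 6)
  sim <- simulate_ppi(cfg)
  ont <- simulate_ontology_and_calls(sim$truth, cfg)
  expect_setequal(unique(ont$dag$parent), "BRAIN")
  expect_equal(nrow(ont$dag), 6)
  expect_true(all(ont$calls$term %in% ont$dag$child))
  # planted association raises presence rate in the planted region
  comm <- sim$truth$community_of_gene
  planted <- ont$truth$enriched_region_of_community
  rate <- function(genes, region) {
    mean(genes %in% ont$calls$gene[ont$calls$term == region])
  }
  for (cm in seq_len(cfg$n_communities)) {
    genes_cm <- names(comm)[comm == cm]
    others <- setdiff(ont$dag$child, planted[[as.character(cm)]])
    expect_gt(rate(genes_cm, planted[[as.character(cm)]]),
              mean(vapply(others, function(r) rate(genes_cm, r), 0)))
  }
})

test_that("no planted signal means exchangeable regions", {
  cfg <- sim_config(seed = 8, n_genes = 40, n_communities = 4,
                    region_signal_strength = 1)
  sim <- simulate_ppi(cfg)
  ont <- simulate_ontology_and_calls(sim$truth, cfg)
  # overall presence rate should sit near the 0.3 baseline everywhere
  tab <- table(ont$calls$term)
  rates <- as.vector(tab) / cfg$n_genes
  expect_true(all(abs(rates - 0.3) < 3 * sqrt(0.3 * 0.7 / cfg$n_genes) + 0.02))
})

test_that("crossref generator plants records that pass and fail each rule", {
  cfg <- sim_config(seed = 10, n_genes = 40, n_communities = 4)
  sim <- simulate_ppi(cfg)
  xr <- simulate_crossref(sim$truth, cfg)
  dn <- suppressMessages(filter_denovo(xr$denovo))
  expect_setequal(dn, xr$truth$crossref$denovo_genes)
  expect_true(all(xr$truth$crossref$cnv_genes %in%
                    filter_cnvs(xr$cnvs, xr$gene_intervals)$genes))
  expect_setequal(suppressMessages(select_categories(xr$categories)),
                  xr$truth$crossref$category_genes)
  # records planted to fail: common MAF and single-algorithm CNV never qualify
  expect_false(any(xr$denovo$gene[xr$denovo$maf >= 0.001] %in% dn))
  expect_true(all(xr$cnvs$n_algorithms[!xr$cnvs$de_novo |
                                         xr$cnvs$n_algorithms < 2] < 2 |
                    !xr$cnvs$de_novo[!xr$cnvs$de_novo | xr$cnvs$n_algorithms < 2]))
})

test_that("a fixed config yields byte-identical output files", {
  cfg <- sim_config(seed = 13, n_genes = 25, n_communities = 3, n_cases = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = sprintf("file %s identical", f))
  }
  # a different seed changes at least the VCF
  d3 <- withr::local_tempdir()
  simulate_inputs(sim_config(seed = 14, n_genes = 25, n_communities = 3,
                             n_cases = 30), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})
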