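test_that("toy VCF with one site per failure mode leaves exactly the clean site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_qc_vcf(path)
  vcf <- read_cohort_vcf(path)
  qc <- apply_qc(vcf)
  passing <- qc$sites[qc$sites$site_pass & qc$sites$n_passing_carriers > 0, ]
  expect_equal(passing$key, "1:100:A:T")
  expect_equal(passing$carriers[[1]], "S1")
  # each planted failure lost the site for the planted reason
  failed <- qc$sites[qc$sites$key != "1:100:A:T", ]
  expect_true(all(!failed$site_pass | failed$n_passing_carriers == 0))
})

test_that("QC boundaries follow the printed inequalities", {
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    vcf_record(100, -1.5, c(gt_het(), gt_ref(), gt_ref())), # VQSLOD = -1.5 passes (>=)
    vcf_record(200, 5, c(gt_het(dp = 8), gt_ref(), gt_ref())), # DP = 8 fails (strict >)
    vcf_record(300, 5, c(gt_het(dp = 9, ad_alt = 4), gt_ref(), gt_ref())), # DP = 9 passes
    vcf_record(400, 5, c(gt_het(gq = 20), gt_ref(), gt_ref())), # GQ = 20 fails
    vcf_record(500, 5, c(gt_het(gq = 21), gt_ref(), gt_ref())), # GQ = 21 passes
    vcf_record(600, 5, c(gt_het(dp = 30, ad_alt = 6), gt_ref(), gt_ref())), # AB = 0.2 fails
    vcf_record(700, 5, c(gt_het(dp = 30, ad_alt = 7), gt_ref(), gt_ref())) # AB > 0.2 passes
  )
  writeLines(toy_vcf_lines(recs), path)
  qc <- apply_qc(read_cohort_vcf(path))
  ok <- qc$sites$site_pass & qc$sites$n_passing_carriers > 0
  expect_equal(qc$sites$pos[ok], c(100, 300, 500, 700))
})

test_that("missing QC fields fail closed", {
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    # no VQSLOD key at this site
    paste("1", 100, ".", "A", "T", ".", "PASS", "GENE=G1;CSQ=stop_gain",
          "GT:DP:GQ:AD", gt_het(), gt_ref(), gt_ref(), sep = "\t"),
    vcf_record(200, 5, c("0/1:.:90:.", gt_ref(), gt_ref())) # carrier lacks DP/AD
  )
  writeLines(toy_vcf_lines(recs), path)
  qc <- apply_qc(read_cohort_vcf(path))
  expect_false(qc$sites$site_pass[qc$sites$pos == 100])
  expect_equal(qc$sites$n_passing_carriers[qc$sites$pos == 200], 0L)
})

test_that("multiallelic and malformed VCF rows are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    vcf_record(100, 5, c(gt_het(), gt_ref(), gt_ref())),
    paste("1", 200, ".", "A", "T,G", ".", "PASS", "VQSLOD=5;GENE=G1;CSQ=stop_gain",
          "GT:DP:GQ:AD", gt_het(), gt_ref(), gt_ref(), sep = "\t")
  )
  writeLines(toy_vcf_lines(recs), path)
  expect_error(read_cohort_vcf(path), "line 11.*multiallelic")

  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(c(
    vcf_record(100, 5, c(gt_het(), gt_ref(), gt_ref())),
    "1\t200\t.\tA"
  )), path2)
  expect_error(read_cohort_vcf(path2), "line 11")
})

test_that("population frequency boundaries: 0.1% removed, absent retained", {
  sites <- tibble::tibble(key = c("1:1:A:T", "1:2:A:T", "1:3:A:T", "1:4:A:T"))
  ctrl <- tibble::tibble(
    key = c("1:1:A:T", "1:2:A:T", "1:3:A:T"),
    af = c(0.001, 0.0009999, 0.9995) # boundary, just-below, MAF folds to 0.0005
  )
  kept <- filter_population_frequency(sites, ctrl, 0.001)
  expect_setequal(kept$key, c("1:2:A:T", "1:3:A:T", "1:4:A:T"))
})

test_that("ten-site frequency fixture drops the four planted common sites", {
  sites <- tibble::tibble(key = sprintf("1:%d:A:T", 1:10))
  ctrl <- tibble::tibble(
    key = sprintf("1:%d:A:T", 1:6),
    af = c(0.05, 0.01, 0.002, 0.001, 0.0005, 0.00001)
  )
  expect_equal(nrow(filter_population_frequency(sites, ctrl, 0.001)), 6)
})

test_that("LoF selection keeps the five LoF classes and drops or maps others", {
  sites <- tibble::tibble(
    key = sprintf("1:%d:A:T", 1:8),
    consequence = c(lof_classes(), "other", "missense_variant", NA)
  )
  expect_message(kept <- select_lof(sites), "missense_variant")
  expect_equal(kept$consequence, lof_classes())
})

test_that("candidate restriction is case-insensitive and whitespace-tolerant", {
  sites <- tibble::tibble(
    key = sprintf("1:%d:A:T", 1:3),
    gene = c("GeneA", "GENEB", "GENEC"),
    consequence = "stop_gain",
    carriers = list("S1", "S2", character())
  )
  qv <- restrict_to_candidates(sites, c(" genea ", "geneb"))
  expect_equal(qv$gene, c("GeneA", "GENEB")) # GENEC off-list; carrier sets kept
  expect_error(restrict_to_candidates(sites, character()), "empty")
  expect_warning(restrict_to_candidates(sites, "NOPE"), "no sites")
})

test_that("site-level filters commute", {
  cfg <- sim_config(seed = 17, n_genes = 30, n_communities = 3, n_cases = 40)
  sim <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, sim$truth)
  genes <- names(sim$truth$community_of_gene)
  qc <- apply_qc(cohort)
  base <- qc$sites[qc$sites$site_pass, ]
  ctrl <- cohort$control_af

  a <- base |>
    filter_population_frequency(ctrl, 0.001) |>
    select_lof() |>
    restrict_to_candidates(genes)
  b <- select_lof(base) |>
    filter_population_frequency(ctrl, 0.001) |>
    restrict_to_candidates(genes)
  c1 <- base[norm_gene_for_test(base$gene) %in% norm_gene_for_test(genes), ] |>
    select_lof() |>
    filter_population_frequency(ctrl, 0.001) |>
    restrict_to_candidates(genes)
  expect_setequal(a$key, b$key)
  expect_setequal(a$key, c1$key)
})

test_that("cohort summary reproduces the printed headline arithmetic", {
  # 446 carriers of 3938 cases -> 11%; 208 of 1216 candidate genes -> 17%
  qv <- tibble::tibble(
    key = sprintf("1:%d:A:T", 1:356),
    gene = rep(sprintf("G%03d", 1:208), length.out = 356),
    consequence = "stop_gain",
    # 90 variants with two distinct carriers + 266 private = 446 distinct cases
    carriers = lapply(1:356, function(i) {
      if (i <= 90) sprintf("A%03d_%d", i, 1:2) else sprintf("B%03d", i)
    })
  )
  s <- summarize_cohort(qv, n_cohort = 3938, n_candidate_genes = 1216)
  expect_equal(s$n_variants, 356)
  expect_equal(s$n_genes, 208)
  expect_equal(s$n_carrier_cases, 446)
  expect_equal(s$pct_cases, 11)
  expect_equal(s$pct_genes, 17)
})

test_that("sharing histogram counts private and shared variants", {
  qv <- dplyr::bind_rows(
    qv_row("1:1:A:T", "G1", c("A", "B")),
    qv_row("1:2:A:T", "G1", "A"),
    qv_row("1:3:A:T", "G2", c("A", "B", "C")),
    qv_row("1:4:A:T", "G3", "D")
  )
  s <- summarize_cohort(qv, n_cohort = 100, n_candidate_genes = 10)
  expect_equal(s$n_private, 2)
  hist <- s$sharing[[1]]
  expect_equal(sum(hist$n_variants), s$n_variants)
  expect_equal(hist$n_variants[hist$carriers_per_variant == 1], 2L)
  expect_equal(hist$n_variants[hist$carriers_per_variant == 3], 1L)
})

test_that("empty qualifying table gives an all-zero summary", {
  qv <- qv_row(character(), character(), character())[0, ]
  s <- summarize_cohort(qv, n_cohort = 100, n_candidate_genes = 10)
  expect_equal(s$n_variants, 0)
  expect_equal(s$n_carrier_cases, 0)
  expect_equal(s$pct_cases, 0)
  expect_error(summarize_cohort(qv, 0, 10), "positive")
})

test_that("per-gene burden matches the printed per-gene percentages", {
  # 11 distinct carriers among 3938 cases -> 0.3%; 9 -> 0.2%
  qv <- dplyr::bind_rows(
    lapply(1:8, function(i) {
      qv_row(sprintf("1:%d:A:T", i), "PDE11A_LIKE",
             sprintf("CASE%02d", c(i, 11)[seq_len(1 + (i <= 3))])
      )
    }),
    lapply(1:6, function(i) {
      qv_row(sprintf("2:%d:A:T", i), "SYTL3_LIKE",
             sprintf("OTH%02d", c(i, 9)[seq_len(1 + (i <= 3))])
      )
    })
  )
  burden <- per_gene_burden(qv, n_cohort = 3938)
  expect_equal(burden$gene, c("PDE11A_LIKE", "SYTL3_LIKE")) # sorted by n_variants
  pd <- burden[burden$gene == "PDE11A_LIKE", ]
  expect_equal(pd$n_variants, 8)
  expect_equal(pd$n_cases, 9) # carriers of multiple variants counted once
  sy <- burden[burden$gene == "SYTL3_LIKE", ]
  expect_equal(sy$pct_cases, 0.2)
  # exact printed percentages for the stated carrier counts
  direct <- per_gene_burden(
    dplyr::bind_rows(
      qv_row("1:1:A:T", "GA", sprintf("C%02d", 1:11)),
      qv_row("2:1:A:T", "GB", sprintf("D%02d", 1:9))
    ),
    n_cohort = 3938
  )
  expect_equal(direct$pct_cases[direct$gene == "GA"], 0.3)
  expect_equal(direct$pct_cases[direct$gene == "GB"], 0.2)
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(0.25, 1), 0.3)
  expect_equal(round_half_away(-0.25, 1), -0.3)
  expect_equal(round_half_away(11.5), 12)
  expect_equal(round_half_away(0.2793 * 100, 0) / 100, 0.28)
})

test_that("VCF writer round-trips through the reader", {
  cfg <- sim_config(seed = 19, n_genes = 15, n_communities = 3, n_cases = 12)
  sim <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, sim$truth)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(cohort, path)
  back <- read_cohort_vcf(path)
  expect_equal(back$samples, cohort$samples)
  expect_setequal(back$sites$key, cohort$sites$key)
  ord <- match(cohort$sites$key, back$sites$key)
  expect_equal(back$sites$vqslod[ord], cohort$sites$vqslod)
  expect_equal(back$sites$consequence[ord], cohort$sites$consequence)
  g1 <- dplyr::arrange(back$geno, key, sample)
  g2 <- dplyr::arrange(cohort$geno, key, sample) |>
    dplyr::mutate(dplyr::across(c("gt", "dp", "gq", "ad_ref", "ad_alt"), as.numeric))
  g1 <- dplyr::mutate(g1, dplyr::across(c("gt", "dp", "gq", "ad_ref", "ad_alt"), as.numeric))
  expect_equal(g1$gt, g2$gt)
  expect_equal(g1$dp, g2$dp)
  expect_equal(g1$ad_alt, g2$ad_alt)
})
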