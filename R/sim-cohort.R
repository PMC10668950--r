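LOF_CLASSES <- c(
  "frameshift", "stop_gain", "start_lost", "splice_acceptor", "splice_donor"
)

#' Simulate a case cohort VCF and a control allele-frequency table
#'
#' Emits a synthetic whole-exome-style call set over the genes created by
#' [simulate_ppi()]. A known subset of sites ("planted qualifying") passes
#' every quality, frequency, consequence and candidate-list filter, with their
#' carriers recorded in the planted truth. Contaminant sites are planted to
#' fail exactly one named filter each:
#'
#' * `fail_vqslod` — site-level VQSLOD below the threshold;
#' * `fail_missingness` — missing-genotype fraction above the threshold;
#' * `fail_dp`, `fail_gq`, `fail_ab` — every carrier genotype fails the
#'   depth / genotype-quality / allele-balance check, leaving no carriers;
#' * `fail_frequency` — clean site whose control allele frequency is >= 0.1%;
#' * `fail_lof` — clean rare site with a non-LoF ("other") consequence;
#' * `fail_candidate` — clean rare LoF site in an off-list gene (`X...`).
#'
#' Carrier counts per qualifying site are 1 plus a small binomial excess, so
#' most qualifying variants are private, a minority shared by 2-3 cases.
#'
#' @param cfg A [sim_config()].
#' @param truth Planted truth from [simulate_ppi()] (defines the gene list).
#' @return A list with
#'   * `sites`: tibble of VCF site records (`chrom`, `pos`, `ref`, `alt`,
#'     `key`, `vqslod`, `gene`, `consequence`, `planted` label);
#'   * `geno`: long tibble of per-case genotypes (`key`, `sample`, `gt` in
#'     \{0, 1, NA\}, `dp`, `gq`, `ad_ref`, `ad_alt`);
#'   * `control_af`: tibble (`chrom`, `pos`, `ref`, `alt`, `af`) — sites
#'     absent from it are unseen in controls;
#'   * `samples`: case identifiers;
#'   * `truth`: input truth with `carrier_cases_by_gene` and `qualifying`
#'     filled in.
#' @export
simulate_cohort <- function(cfg, truth) {
  stopifnot(inherits(cfg, "ns_sim_config"), inherits(truth, "ns_planted_truth"))
  genes <- names(truth$community_of_gene)
  samples <- case_ids(cfg$n_cases)

  with_seed(cfg$seed + 1L, {
    ## ---- plan sites -------------------------------------------------------
    has_lof <- runif(length(genes)) < cfg$lof_rate_per_gene
    n_extra <- rpois(sum(has_lof), 0.25)
    qual_genes <- rep(genes[has_lof], 1L + n_extra)

    has_bg <- runif(length(genes)) < cfg$background_variant_rate
    bg_genes <- genes[has_bg]

    n_qual <- length(qual_genes)
    fc <- cfg$frac_common_contaminant
    n_common <- if (fc > 0 && fc < 1) round(fc * n_qual / (1 - fc)) else 0L
    common_genes <- if (n_common > 0) sample(genes, n_common, replace = TRUE) else character()

    n_qc_each <- 3L
    qc_kinds <- c("fail_vqslod", "fail_missingness", "fail_dp", "fail_gq", "fail_ab")
    qc_genes <- sample(genes, n_qc_each * length(qc_kinds), replace = TRUE)
    offlist_genes <- sprintf("X%04d", seq_len(3L))

    plan <- tibble(
      gene = c(qual_genes, bg_genes, common_genes, qc_genes, offlist_genes),
      planted = c(
        rep("qualifying", n_qual),
        rep("fail_lof", length(bg_genes)),
        rep("fail_frequency", length(common_genes)),
        rep(qc_kinds, each = n_qc_each),
        rep("fail_candidate", length(offlist_genes))
      )
    )
    n_sites <- nrow(plan)

    ## ---- site-level fields ------------------------------------------------
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    plan <- plan |>
      mutate(
        chrom = as.character(sample(1:22, n_sites, replace = TRUE)),
        pos = sample(1e6:5e7, n_sites),
        ref = ref, alt = alt,
        key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
        vqslod = round(ifelse(.data$planted == "fail_vqslod",
          runif(n_sites, -6, -2), runif(n_sites, 0, 10)
        ), 2),
        consequence = ifelse(.data$planted == "fail_lof", "other",
          sample(LOF_CLASSES, n_sites, replace = TRUE)
        )
      )

    ## ---- genotypes --------------------------------------------------------
    n_carriers <- 1L + rbinom(n_sites, 2L, 0.06)
    carriers <- map(n_carriers, function(k) sample(samples, k))

    miss_frac <- ifelse(plan$planted == "fail_missingness",
      runif(n_sites, 0.12, 0.20), runif(n_sites, 0, 0.04)
    )

    geno <- pmap(
      list(plan$key, carriers, miss_frac, plan$planted),
      function(key, carr, mf, kind) {
        dp <- sample(20:60, cfg$n_cases, replace = TRUE)
        gq <- sample(60:99, cfg$n_cases, replace = TRUE)
        gt <- integer(cfg$n_cases)
        ad_alt <- integer(cfg$n_cases)
        idx <- match(carr, samples)
        gt[idx] <- 1L
        # carrier genotype fields, by planted failure mode
        if (kind == "fail_dp") {
          dp[idx] <- sample(3:8, length(idx), replace = TRUE)
          ad_alt[idx] <- pmax(1L, round(dp[idx] * 0.5))
        } else if (kind == "fail_gq") {
          gq[idx] <- sample(5:20, length(idx), replace = TRUE)
          ad_alt[idx] <- round(dp[idx] * 0.5)
        } else if (kind == "fail_ab") {
          ad_alt[idx] <- pmax(1L, floor(dp[idx] * 0.15))
        } else {
          ad_alt[idx] <- round(dp[idx] * runif(length(idx), 0.35, 0.6))
        }
        # missing genotypes, never on carriers
        n_miss <- round(mf * cfg$n_cases)
        pool <- setdiff(seq_len(cfg$n_cases), idx)
        miss <- if (n_miss > 0) sample(pool, min(n_miss, length(pool))) else integer()
        gt[miss] <- NA_integer_
        tibble(
          key = key, sample = samples, gt = gt, dp = dp, gq = gq,
          ad_ref = dp - ad_alt, ad_alt = ad_alt
        )
      }
    ) |>
      list_rbind()

    ## ---- control allele frequencies --------------------------------------
    n2 <- 2 * cfg$n_controls_freq_table
    common <- plan |>
      filter(.data$planted == "fail_frequency") |>
      mutate(af = round(runif(n(), 0.001, 0.05), 6))
    seen_rare <- plan |>
      filter(.data$planted != "fail_frequency") |>
      slice_sample(prop = 0.3) |>
      mutate(af = round(sample(1:5, n(), replace = TRUE) / n2, 8))
    control_af <- bind_rows(common, seen_rare) |>
      select("chrom", "pos", "ref", "alt", "af", "key") |>
      arrange(.data$chrom, .data$pos)
  })

  qual_idx <- which(plan$planted == "qualifying")
  qualifying <- plan[qual_idx, ] |>
    mutate(carriers = carriers[qual_idx]) |>
    select("key", "gene", "consequence", "carriers")
  truth$qualifying <- qualifying
  truth$carrier_cases_by_gene <- qualifying |>
    select("gene", "carriers") |>
    unnest("carriers") |>
    distinct() |>
    summarise(cases = list(sort(.data$carriers)), .by = "gene") |>
    (\(d) setNames(d$cases, d$gene))()

  list(
    sites = plan |>
      select("chrom", "pos", "ref", "alt", "key", "vqslod", "gene",
             "consequence", "planted") |>
      arrange(as.integer(.data$chrom), .data$pos),
    geno = geno,
    control_af = control_af,
    samples = samples,
    truth = truth
  )
}

#' Write a synthetic cohort as a VCFv4.2 file
#'
#' Serialises the output of [simulate_cohort()] as VCFv4.2 with one ALT per
#' record, `VQSLOD`, `GENE` and `CSQ` INFO keys, and `GT:DP:GQ:AD` genotype
#' fields, so the file round-trips through [read_cohort_vcf()].
#'
#' @param cohort Output of [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  sites <- cohort$sites
  wide_gt <- cohort$geno |>
    mutate(
      field = paste0(
        ifelse(is.na(.data$gt), "./.", ifelse(.data$gt > 0, "0/1", "0/0")),
        ":", .data$dp, ":", .data$gq, ":", .data$ad_ref, ",", .data$ad_alt
      )
    ) |>
    select("key", "sample", "field") |>
    pivot_wider(names_from = "sample", values_from = "field")
  wide_gt <- wide_gt[match(sites$key, wide_gt$key), , drop = FALSE]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nsnet-simulate",
    '##INFO=<ID=VQSLOD,Number=1,Type=Float,Description="Variant quality score log-odds">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
    sprintf("VQSLOD=%s;GENE=%s;CSQ=%s", sites$vqslod, sites$gene, sites$consequence),
    "GT:DP:GQ:AD",
    do.call(paste, c(wide_gt[, -1, drop = FALSE], sep = "\t")),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a control allele-frequency table
#'
#' @param control_af Tibble with `chrom`, `pos`, `ref`, `alt`, `af` (a `key`
#'   column, if present, is not written; it is recomputed on read).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_control_af <- function(control_af, path) {
  readr::write_tsv(select(control_af, "chrom", "pos", "ref", "alt", "af"), path)
  invisible(path)
}
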