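#' Simulate cross-dataset validation evidence tables
#'
#' Creates the three external-evidence inputs used for network gene
#' validation, each with records planted to pass and records planted to fail
#' every rule:
#'
#' * a de novo SNV table (`gene`, `maf`, `sift`, `polyphen`) — qualifying
#'   records have population MAF < 0.001 and a damaging SIFT *or* PolyPhen
#'   label; fails include a common variant (MAF 0.01), benign-only labels,
#'   and a record with both labels missing;
#' * a de novo CNV table (`chrom`, `start`, `end`, `de_novo`,
#'   `n_algorithms`) plus a gene interval table — qualifying CNVs are
#'   de novo and detected by at least two algorithms and overlap a planted
#'   gene's interval by >= 1 bp; fails include single-algorithm calls,
#'   inherited calls and calls overlapping no gene;
#' * a category table (`gene`, `category`) — qualifying categories are
#'   "1", "2" and any syndromic flag ("S", "1S", "2S", "3S"); plain "3"
#'   does not qualify.
#'
#' @param truth Planted truth from [simulate_ppi()].
#' @param cfg A [sim_config()].
#' @return A list with `denovo`, `cnvs`, `gene_intervals`, `categories`
#'   tibbles and `truth` updated with a `crossref` slot recording the planted
#'   qualifying gene sets per evidence source.
#' @export
simulate_crossref <- function(truth, cfg) {
  stopifnot(inherits(cfg, "ns_sim_config"), inherits(truth, "ns_planted_truth"))
  genes <- names(truth$community_of_gene)

  with_seed(cfg$seed + 4L, {
    ## gene intervals (synthetic coordinates, 1-based inclusive)
    gene_intervals <- tibble(
      gene = genes,
      chrom = as.character(sample(1:22, length(genes), replace = TRUE)),
      start = sample(1e6:8e7, length(genes))
    ) |>
      mutate(end = .data$start + sample(2e4:8e4, length(genes)))

    ## de novo SNVs
    n_hit <- max(3L, round(0.08 * length(genes)))
    dn_hit_genes <- sample(genes, n_hit)
    dn_pass <- tibble(
      gene = dn_hit_genes,
      maf = round(runif(n_hit, 0, 0.0009), 6),
      sift = sample(c("deleterious", "tolerated"), n_hit, replace = TRUE),
      polyphen = sample(c("probably_damaging", "possibly_damaging", "benign"),
                        n_hit, replace = TRUE)
    ) |>
      mutate(sift = ifelse(
        .data$sift == "tolerated" & .data$polyphen == "benign",
        "deleterious", .data$sift
      ))
    dn_fail_genes <- sample(setdiff(genes, dn_hit_genes), 4)
    dn_fail <- tibble(
      gene = dn_fail_genes,
      maf = c(0.01, 0.001, 0.0001, 0.0002),
      sift = c("deleterious", "deleterious", "tolerated", NA),
      polyphen = c("probably_damaging", "benign", "benign", NA)
    )
    denovo <- bind_rows(dn_pass, dn_fail) |> arrange(.data$gene)

    ## de novo CNVs
    n_cnv <- max(3L, round(0.05 * length(genes)))
    cnv_hit_genes <- sample(setdiff(genes, dn_hit_genes), n_cnv)
    hit_iv <- gene_intervals[match(cnv_hit_genes, gene_intervals$gene), ]
    cnv_pass <- tibble(
      chrom = hit_iv$chrom,
      start = hit_iv$start - sample(1e3:1e4, n_cnv),
      end = hit_iv$start + sample(1e3:1e4, n_cnv),
      de_novo = TRUE,
      n_algorithms = sample(2:3, n_cnv, replace = TRUE)
    )
    other_iv <- gene_intervals[match(sample(setdiff(genes, cnv_hit_genes), 3),
                                     gene_intervals$gene), ]
    cnv_fail <- tibble(
      chrom = c(other_iv$chrom[1:2], "1"),
      start = c(other_iv$start[1:2] - 500L, 1L),
      end = c(other_iv$end[1:2] + 500L, 1000L),
      de_novo = c(TRUE, FALSE, TRUE),
      n_algorithms = c(1L, 2L, 2L) # single-algorithm, inherited, gene-free
    )
    cnvs <- bind_rows(cnv_pass, cnv_fail)

    ## curated categories
    n_cat <- max(3L, round(0.06 * length(genes)))
    cat_hit_genes <- sample(genes, n_cat)
    cat_pass <- tibble(
      gene = cat_hit_genes,
      category = sample(c("1", "2", "S", "2S", "1S"), n_cat, replace = TRUE)
    )
    cat_fail_genes <- sample(setdiff(genes, cat_hit_genes), 3)
    cat_fail <- tibble(gene = cat_fail_genes, category = c("3", "4", "3"))
    categories <- bind_rows(cat_pass, cat_fail) |> arrange(.data$gene)
  })

  truth$crossref <- list(
    denovo_genes = sort(dn_pass$gene),
    cnv_genes = sort(cnv_hit_genes),
    category_genes = sort(cat_pass$gene)
  )
  list(
    denovo = denovo, cnvs = cnvs, gene_intervals = gene_intervals,
    categories = categories, truth = truth
  )
}
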