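#' Filter de novo SNV records to qualifying genes
#'
#' A record qualifies iff its population MAF is strictly below 0.001 and it
#' is predicted damaging by SIFT *or* PolyPhen (`sift == "deleterious"` or
#' `polyphen` in `"probably_damaging"`/`"possibly_damaging"`; labels are
#' normalised to lower case with spaces mapped to underscores). Records
#' missing both labels never qualify.
#'
#' @param records Tibble (`gene`, `maf`, `sift`, `polyphen`).
#' @param maf_max Exclusive MAF bound (default 0.001).
#' @return Sorted character vector of qualifying gene symbols.
#' @export
filter_denovo <- function(records, maf_max = 0.001) {
  norm_label <- function(x) gsub(" ", "_", tolower(trimws(as.character(x))))
  damaging <- records |>
    mutate(
      sift = norm_label(.data$sift),
      polyphen = norm_label(.data$polyphen),
      qual = !is.na(.data$maf) & .data$maf < maf_max &
        ((!is.na(.data$sift) & .data$sift == "deleterious") |
           (!is.na(.data$polyphen) &
              .data$polyphen %in% c("probably_damaging", "possibly_damaging")))
    )
  n_unlabelled <- sum(is.na(damaging$sift) & is.na(damaging$polyphen))
  if (n_unlabelled > 0) {
    inform(sprintf("filter_denovo: %d record(s) missing both labels; non-qualifying",
                   n_unlabelled))
  }
  sort(unique(damaging$gene[damaging$qual]))
}

#' Filter de novo CNVs and find the genes they hit
#'
#' A CNV qualifies iff it is flagged de novo and was detected by at least two
#' algorithms. A gene is hit iff its interval overlaps a qualifying CNV by at
#' least 1 bp; intervals are closed and 1-based, so a CNV ending exactly at a
#' gene's start overlaps it.
#'
#' @param records CNV tibble (`chrom`, `start`, `end`, `de_novo`,
#'   `n_algorithms`).
#' @param gene_intervals Tibble (`gene`, `chrom`, `start`, `end`), same
#'   coordinate convention.
#' @return A list with `cnvs` (qualifying CNV rows, with an added `cnv_id`)
#'   and `genes` (sorted hit gene symbols).
#' @export
filter_cnvs <- function(records, gene_intervals) {
  malformed <- !is.finite(records$start) | !is.finite(records$end) |
    records$start > records$end
  if (any(malformed)) {
    inform(sprintf("filter_cnvs: rejected %d malformed interval row(s)", sum(malformed)))
  }
  qual <- records |>
    filter(!malformed, .data$de_novo, .data$n_algorithms >= 2) |>
    mutate(cnv_id = row_number())
  hits <- qual |>
    inner_join(gene_intervals, by = "chrom", suffix = c("", "_gene"),
               relationship = "many-to-many") |>
    filter(.data$start <= .data$end_gene, .data$start_gene <= .data$end)
  list(cnvs = qual, genes = sort(unique(hits$gene)))
}

#' Select genes in the strongest evidence categories
#'
#' Keeps genes whose category parses to score 1 or 2, or carries the
#' syndromic flag `S` (so `"2S"` qualifies on both grounds and `"3S"` via the
#' flag, while plain `"3"` does not). Unparseable categories are skipped with
#' a message.
#'
#' @param entries Tibble (`gene`, `category`).
#' @return Sorted character vector of qualifying gene symbols.
#' @export
select_categories <- function(entries) {
  cat_raw <- toupper(trimws(as.character(entries$category)))
  parsed <- stringr::str_match(cat_raw, "^([123]?)(S?)$")
  bad <- is.na(parsed[, 1]) | cat_raw == ""
  if (any(bad)) {
    inform(sprintf("select_categories: skipped %d unparseable category value(s): %s",
                   sum(bad), paste(unique(cat_raw[bad]), collapse = ", ")))
  }
  score <- parsed[, 2]
  syndromic <- parsed[, 3] == "S"
  keep <- !bad & (score %in% c("1", "2") | syndromic)
  sort(unique(entries$gene[keep]))
}

#' Tally cross-dataset evidence per gene and per community
#'
#' Flags each network gene by presence in the de novo SNV, de novo CNV and
#' category evidence sets (symbols matched case-insensitively), plus a union
#' flag counting each gene once however many sources support it, and sums the
#' flags per community.
#'
#' @param network_genes Character vector of network gene symbols.
#' @param partition An `ns_partition` or named membership vector covering the
#'   network genes.
#' @param denovo_genes,cnv_genes,category_genes Evidence gene sets (e.g. from
#'   [filter_denovo()], [filter_cnvs()], [select_categories()]).
#' @return A list with `per_gene` (tibble `gene`, `community`, `denovo`,
#'   `cnv`, `category`, `any_evidence`) and `per_community` (tibble
#'   `community`, `n_genes`, `n_denovo`, `n_cnv`, `n_category`,
#'   `n_any_evidence`).
#' @export
tally_evidence <- function(network_genes, partition,
                           denovo_genes, cnv_genes, category_genes) {
  memb <- if (inherits(partition, "ns_partition")) partition$membership else partition
  per_gene <- tibble(gene = sort(unique(network_genes))) |>
    mutate(
      community = as.integer(memb[match(norm_gene(.data$gene), norm_gene(names(memb)))]),
      denovo = norm_gene(.data$gene) %in% norm_gene(denovo_genes),
      cnv = norm_gene(.data$gene) %in% norm_gene(cnv_genes),
      category = norm_gene(.data$gene) %in% norm_gene(category_genes),
      any_evidence = .data$denovo | .data$cnv | .data$category
    )
  per_community <- per_gene |>
    summarise(
      n_genes = n(),
      n_denovo = sum(.data$denovo),
      n_cnv = sum(.data$cnv),
      n_category = sum(.data$category),
      n_any_evidence = sum(.data$any_evidence),
      .by = "community"
    ) |>
    arrange(.data$community)
  list(per_gene = per_gene, per_community = per_community)
}
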