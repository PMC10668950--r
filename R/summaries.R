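#' Cohort-level summary of qualifying variants
#'
#' Tallies the qualifying-variant table the way the headline results are
#' reported: number of variants, genes hit, distinct carrier cases, the
#' percentage of the cohort carrying at least one qualifying variant and the
#' percentage of candidate genes hit (both rounded half-away-from-zero to the
#' nearest integer), the carriers-per-variant sharing histogram, and the
#' count of private variants (exactly one carrier).
#'
#' @param qv Qualifying-variant tibble ([restrict_to_candidates()]).
#' @param n_cohort Number of cases analysed (> 0).
#' @param n_candidate_genes Size of the candidate gene list (> 0).
#' @return One-row tibble with columns `n_cohort`, `n_carrier_cases`,
#'   `n_variants`, `n_genes`, `n_candidate_genes`, `pct_cases`, `pct_genes`,
#'   `n_private`, and list-column `sharing` (tibble `carriers_per_variant`,
#'   `n_variants`).
#' @export
#' @examples
#' qv <- tibble::tibble(
#'   key = c("1:1:A:T", "1:2:A:T"), gene = c("G1", "G2"),
#'   consequence = "stop_gain",
#'   carriers = list("CASE1", c("CASE1", "CASE2"))
#' )
#' summarize_cohort(qv, n_cohort = 100, n_candidate_genes = 10)
summarize_cohort <- function(qv, n_cohort, n_candidate_genes) {
  if (n_cohort <= 0 || n_candidate_genes <= 0) {
    stop_nsnet("summarize_cohort: n_cohort and n_candidate_genes must be positive")
  }
  n_carriers_per_variant <- lengths(qv$carriers)
  n_carrier_cases <- length(unique(unlist(qv$carriers)))
  sharing <- if (nrow(qv) > 0) {
    tibble(carriers_per_variant = n_carriers_per_variant) |>
      count(.data$carriers_per_variant, name = "n_variants") |>
      arrange(.data$carriers_per_variant)
  } else {
    tibble(carriers_per_variant = integer(), n_variants = integer())
  }
  tibble(
    n_cohort = as.integer(n_cohort),
    n_carrier_cases = n_carrier_cases,
    n_variants = nrow(qv),
    n_genes = length(unique(qv$gene)),
    n_candidate_genes = as.integer(n_candidate_genes),
    pct_cases = round_half_away(100 * n_carrier_cases / n_cohort),
    pct_genes = round_half_away(100 * length(unique(qv$gene)) / n_candidate_genes),
    n_private = sum(n_carriers_per_variant == 1L),
    sharing = list(sharing)
  )
}

#' Per-gene burden of qualifying variants
#'
#' One row per gene carrying at least one qualifying variant: variant count,
#' distinct carrier cases (a case with several variants in the same gene
#' counts once) and the percentage of the cohort those cases represent,
#' rounded half-away-from-zero to one decimal. Sorted by decreasing variant
#' count, ties broken by gene symbol.
#'
#' @param qv Qualifying-variant tibble.
#' @param n_cohort Number of cases analysed (> 0).
#' @return Tibble (`gene`, `n_variants`, `n_cases`, `pct_cases`).
#' @export
per_gene_burden <- function(qv, n_cohort) {
  if (n_cohort <= 0) {
    stop_nsnet("per_gene_burden: n_cohort must be positive")
  }
  qv |>
    as_tibble() |>
    summarise(
      n_variants = n(),
      n_cases = length(unique(unlist(.data$carriers))),
      .by = "gene"
    ) |>
    mutate(pct_cases = round_half_away(100 * .data$n_cases / n_cohort, 1)) |>
    arrange(desc(.data$n_variants), .data$gene)
}
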