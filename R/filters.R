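#' Loss-of-function consequence classes
#'
#' The consequence classes treated as loss-of-function: frameshift,
#' stop gain, start lost, splice acceptor and splice donor. Any other
#' annotation maps to `"other"`.
#'
#' @return Character vector of the five LoF class names.
#' @export
lof_classes <- function() LOF_CLASSES

#' Remove sites that are common in the control population
#'
#' A site is retained iff it is absent from the control table (absence from a
#' large control cohort is the strongest rarity evidence, frequency 0) or its
#' control minor allele frequency is strictly below `maf_max`. MAF is
#' `min(af, 1 - af)` of the ALT allele.
#'
#' @param sites Site tibble with a `key` column.
#' @param control_af Control table from [read_control_af()] (needs `key`,
#'   `af`).
#' @param maf_max Exclusive frequency bound (default 0.001, i.e. 0.1%).
#' @return Filtered site tibble.
#' @export
filter_population_frequency <- function(sites, control_af, maf_max = 0.001) {
  af <- control_af$af[match(sites$key, control_af$key)]
  maf <- pmin(af, 1 - af)
  sites[is.na(maf) | maf < maf_max, , drop = FALSE]
}

#' Keep loss-of-function sites
#'
#' Retains sites whose annotated consequence is one of [lof_classes()].
#' Unknown consequence strings are mapped to `"other"` (with a message) and
#' therefore dropped.
#'
#' @param sites Site tibble with a `consequence` column.
#' @return Filtered site tibble.
#' @export
select_lof <- function(sites) {
  cons <- sites$consequence
  unknown <- !is.na(cons) & !cons %in% c(LOF_CLASSES, "other")
  if (any(unknown)) {
    inform(sprintf(
      "select_lof: %d unknown consequence string(s) mapped to 'other': %s",
      sum(unknown), paste(unique(cons[unknown]), collapse = ", ")
    ))
    cons[unknown] <- "other"
  }
  cons[is.na(cons)] <- "other"
  sites[cons %in% LOF_CLASSES, , drop = FALSE]
}

#' Restrict sites to candidate genes and build the qualifying-variant table
#'
#' Keeps sites whose gene is in the candidate list (symbols compared
#' case-insensitively after whitespace stripping) and returns the
#' qualifying-variant table: one row per variant with its gene, consequence
#' and the set of carrier case ids. Rows with an empty carrier set are
#' dropped (a variant with no passing carrier is not observed in the cohort).
#'
#' @param sites Site tibble that already passed QC, frequency and consequence
#'   filters; needs `key`, `gene`, `consequence` and list-column `carriers`.
#' @param gene_list Character vector of candidate gene symbols.
#' @return Qualifying-variant tibble (`key`, `gene`, `consequence`,
#'   `carriers`), unique by `key`.
#' @export
restrict_to_candidates <- function(sites, gene_list) {
  if (length(gene_list) == 0) {
    stop_nsnet("restrict_to_candidates: empty candidate gene list")
  }
  keep <- norm_gene(sites$gene) %in% norm_gene(gene_list)
  out <- sites[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("restrict_to_candidates: no sites in candidate genes")
  }
  out <- out |>
    filter(lengths(.data$carriers) > 0) |>
    select("key", "gene", "consequence", "carriers") |>
    distinct(.data$key, .keep_all = TRUE)
  class(out) <- c("ns_qualifying", class(out))
  out
}

#' Run the full qualifying-variant filter chain
#'
#' Convenience wrapper: quality control, population-frequency filter,
#' loss-of-function selection and candidate-gene restriction, in that order.
#' The three site-level filters commute, so any order yields the same table.
#'
#' @param vcf Cohort tables from [read_cohort_vcf()] or [simulate_cohort()].
#' @param control_af Control table from [read_control_af()] (a `key` and `af`
#'   column), or the `control_af` element of [simulate_cohort()].
#' @param gene_list Candidate gene symbols.
#' @param thresholds A [qc_thresholds()].
#' @return Qualifying-variant tibble, see [restrict_to_candidates()].
#' @export
qualifying_variants <- function(vcf, control_af, gene_list,
                                thresholds = qc_thresholds()) {
  if (!"key" %in% names(control_af)) {
    control_af <- control_af |>
      mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  }
  qc <- apply_qc(vcf, thresholds)
  qc$sites |>
    filter(.data$site_pass) |>
    filter_population_frequency(control_af, thresholds$maf_max) |>
    select_lof() |>
    restrict_to_candidates(gene_list)
}
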