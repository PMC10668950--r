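#' Quality-control thresholds for cohort variant filtering
#'
#' Defaults follow the conventional exome QC recipe for this analysis:
#' sites need `VQSLOD >= -1.5` (non-strict) and case missingness `< 10%`
#' (strict); non-reference genotypes need `DP > 8`, `GQ > 20` and allele
#' balance `> 0.2` (all strict). The population-frequency bound is
#' `MAF < 0.1%` (strict).
#'
#' @param vqslod_min Minimum site VQSLOD (inclusive).
#' @param dp_min Genotype read depth bound (exclusive: `DP = 8` fails).
#' @param gq_min Genotype quality bound (exclusive).
#' @param allele_balance_min Alt-read fraction bound (exclusive), applied to
#'   genotypes carrying the ALT allele.
#' @param missingness_max Maximum missing-genotype fraction among cases
#'   (exclusive).
#' @param maf_max Control minor-allele-frequency bound (exclusive:
#'   `MAF = 0.001` is removed).
#' @return A list of class `ns_qc_thresholds`.
#' @export
qc_thresholds <- function(vqslod_min = -1.5,
                          dp_min = 8,
                          gq_min = 20,
                          allele_balance_min = 0.2,
                          missingness_max = 0.10,
                          maf_max = 0.001) {
  fr <- c(allele_balance_min = allele_balance_min,
          missingness_max = missingness_max, maf_max = maf_max)
  if (any(!is.finite(fr) | fr < 0 | fr > 1)) {
    stop_nsnet("qc_thresholds: fractions must lie in [0,1]")
  }
  structure(
    list(
      vqslod_min = vqslod_min, dp_min = dp_min, gq_min = gq_min,
      allele_balance_min = allele_balance_min,
      missingness_max = missingness_max, maf_max = maf_max
    ),
    class = "ns_qc_thresholds"
  )
}

#' Apply genotype- and site-level quality control
#'
#' A non-reference genotype passes iff `DP > dp_min`, `GQ > gq_min` and its
#' allele balance (`ad_alt / (ad_ref + ad_alt)`) `> allele_balance_min`. A
#' site passes iff `VQSLOD >= vqslod_min` and its missing-genotype fraction
#' among cases is `< missingness_max`. Any absent field makes the genotype or
#' site fail closed. A site contributes qualifying carriers only when the
#' site passes and at least one carrier genotype passes.
#'
#' @param vcf Cohort tables from [read_cohort_vcf()] or [simulate_cohort()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with
#'   * `sites`: input site tibble plus `site_pass`, `missingness`,
#'     `n_passing_carriers`, and list-column `carriers` (passing carrier
#'     sample ids);
#'   * `carriers`: long tibble of passing carrier genotypes.
#' @export
apply_qc <- function(vcf, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "ns_qc_thresholds"))
  th <- thresholds

  geno <- vcf$geno |>
    mutate(
      ab = .data$ad_alt / (.data$ad_ref + .data$ad_alt),
      geno_pass = !is.na(.data$gt) & .data$gt > 0 &
        !is.na(.data$dp) & .data$dp > th$dp_min &
        !is.na(.data$gq) & .data$gq > th$gq_min &
        !is.na(.data$ab) & .data$ab > th$allele_balance_min
    )

  site_geno <- geno |>
    summarise(
      missingness = mean(is.na(.data$gt)),
      carriers = list(sort(.data$sample[.data$geno_pass])),
      .by = "key"
    )

  sites <- vcf$sites |>
    left_join(site_geno, by = "key") |>
    mutate(
      missingness = ifelse(is.na(.data$missingness), 1, .data$missingness),
      carriers = map(.data$carriers, ~ .x %||% character()),
      site_pass = !is.na(.data$vqslod) & .data$vqslod >= th$vqslod_min &
        .data$missingness < th$missingness_max,
      n_passing_carriers = lengths(.data$carriers)
    )

  carriers <- geno |>
    filter(.data$geno_pass) |>
    select("key", "sample", "dp", "gq", "ad_ref", "ad_alt", "ab")

  list(sites = sites, carriers = carriers)
}
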