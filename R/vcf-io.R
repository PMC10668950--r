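#' Read a cohort VCF into site and genotype tables
#'
#' Parses a VCFv4.2 file (via vcfR) into the tabular form the filter chain
#' consumes. Records must be pre-split to a single ALT allele; a multi-ALT
#' row is rejected with its line number. A light pre-scan also reports
#' malformed data lines (wrong column count) by line number. Missing
#' `VQSLOD`, `DP`, `GQ` or `AD` values are kept as `NA` so the corresponding
#' site/genotype fails closed in [apply_qc()].
#'
#' @param path VCF file path.
#' @return A list with
#'   * `sites`: tibble (`chrom`, `pos`, `ref`, `alt`, `key`, `vqslod`,
#'     `gene`, `consequence`);
#'   * `geno`: long tibble (`key`, `sample`, `gt` in \{0, 1, NA\}, `dp`,
#'     `gq`, `ad_ref`, `ad_alt`);
#'   * `samples`: sample identifiers in file order.
#' @export
read_cohort_vcf <- function(path) {
  lines <- readr::read_lines(path)
  is_meta <- startsWith(lines, "##")
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1) {
    stop_nsnet("VCF parse error: expected exactly one #CHROM header line in %s", path)
  }
  n_cols <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  body_idx <- which(!is_meta & seq_along(lines) > hdr_idx & nzchar(lines))
  n_fields <- lengths(strsplit(lines[body_idx], "\t", fixed = TRUE))
  bad <- body_idx[n_fields != n_cols]
  if (length(bad) > 0) {
    stop_nsnet("VCF parse error at line %d: expected %d tab-separated fields, found %d",
               bad[1], n_cols, n_fields[which(body_idx == bad[1])])
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop_nsnet(paste0(
      "VCF parse error at line %d: multiallelic record (ALT = %s); ",
      "split multiallelic sites before filtering"
    ), body_idx[which(multi)[1]], fix$ALT[which(multi)[1]])
  }

  info_get <- function(key) {
    val <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    val
  }
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    key = variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
    vqslod = suppressWarnings(as.numeric(info_get("VQSLOD"))),
    gene = info_get("GENE"),
    consequence = info_get("CSQ")
  )

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(gt_raw)

  gt_alt <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  known <- !is.na(gt_raw) & !gt_raw %in% c("./.", ".|.", ".")
  gt_alt[known] <- stringr::str_count(gt_raw[known], "1")

  ad_split <- stringr::str_split_fixed(ifelse(is.na(ad), ",", ad), ",", 2)
  ad_ref <- suppressWarnings(as.integer(ad_split[, 1]))
  ad_alt <- suppressWarnings(as.integer(ad_split[, 2]))

  geno <- tibble(
    key = rep(sites$key, times = length(samples)),
    sample = rep(samples, each = nrow(sites)),
    gt = as.vector(gt_alt),
    dp = as.vector(dp),
    gq = as.vector(gq),
    ad_ref = as.vector(matrix(ad_ref, nrow(sites))),
    ad_alt = as.vector(matrix(ad_alt, nrow(sites)))
  )

  list(sites = sites, geno = geno, samples = samples)
}
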