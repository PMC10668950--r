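# Hand-constructed fixtures: a toy cohort VCF with one site per QC failure
# mode, and a three-level anatomy DAG for parent-child enrichment tests.

toy_vcf_lines <- function(records, samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=VQSLOD,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="x">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="x">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  c(header, records)
}

vcf_record <- function(pos, vqslod, genos, gene = "GENE1",
                       csq = "stop_gain", chrom = "1", ref = "A", alt = "T") {
  paste(
    chrom, pos, ".", ref, alt, ".", "PASS",
    sprintf("VQSLOD=%s;GENE=%s;CSQ=%s", vqslod, gene, csq),
    "GT:DP:GQ:AD", paste(genos, collapse = "\t"),
    sep = "\t"
  )
}

gt_ref <- function(dp = 30, gq = 90) sprintf("0/0:%d:%d:%d,0", dp, gq, dp)
gt_het <- function(dp = 30, gq = 90, ad_alt = NULL) {
  ad_alt <- ad_alt %||% round(dp / 2)
  sprintf("0/1:%d:%d:%d,%d", dp, gq, dp - ad_alt, ad_alt)
}
gt_miss <- function() "./.:0:0:0,0"

# six sites: one per QC failure mode (VQSLOD, missingness, DP, GQ, allele
# balance), plus one clean site at pos 100 carried by S1
write_toy_qc_vcf <- function(path) {
  recs <- c(
    vcf_record(100, 5, c(gt_het(), gt_ref(), gt_ref())), # clean
    vcf_record(200, -2, c(gt_het(), gt_ref(), gt_ref())), # site VQSLOD < -1.5
    vcf_record(300, 5, c(gt_het(), gt_miss(), gt_ref())), # 1/3 missing >= 10%
    vcf_record(400, 5, c(gt_het(dp = 8, ad_alt = 4), gt_ref(), gt_ref())), # DP = 8 fails
    vcf_record(500, 5, c(gt_het(gq = 20), gt_ref(), gt_ref())), # GQ = 20 fails
    vcf_record(600, 5, c(gt_het(dp = 30, ad_alt = 6), gt_ref(), gt_ref())) # AB = 0.2 fails
  )
  writeLines(toy_vcf_lines(recs), path)
  path
}

# three-level part_of DAG:
#   BRAIN <- LOBE1 <- {RA, RB};  BRAIN <- LOBE2 <- {RC}
three_level_dag <- function() {
  tibble::tibble(
    child = c("LOBE1", "LOBE2", "RA", "RB", "RC"),
    parent = c("BRAIN", "BRAIN", "LOBE1", "LOBE1", "LOBE2")
  )
}

flat_dag <- function(regions = c("R1", "R2", "R3")) {
  tibble::tibble(child = regions, parent = "BRAIN")
}

qv_row <- function(key, gene, carriers, consequence = "stop_gain") {
  tibble::tibble(
    key = key, gene = gene, consequence = consequence,
    carriers = list(carriers)
  )
}

norm_gene_for_test <- function(x) toupper(trimws(x))
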