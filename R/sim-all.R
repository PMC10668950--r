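#' Generate every pipeline input, in memory and on disk
#'
#' Runs all synthetic generators in order (network, cohort, pathway sets,
#' ontology and expression calls, cross-dataset evidence) and, when `dir` is
#' given, serialises each to the plain-text formats the pipeline reads:
#'
#' * `ppi_edges.tsv` (geneA, geneB, confidence)
#' * `cohort.vcf` (VCFv4.2), `control_af.tsv`
#' * `genes.txt` (candidate list, one symbol per line)
#' * `pathways.gmt`
#' * `ontology.tsv` (child, parent), `expression_calls.tsv` (gene, term)
#' * `denovo.tsv`, `cnvs.tsv`, `gene_intervals.tsv`, `categories.tsv`
#' * `truth.yaml` (planted ground truth, for validation only)
#'
#' A fixed config (including the seed) yields byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return A list with all generated objects (`edges`, `cohort`, `gene_sets`,
#'   `dag`, `calls`, `denovo`, `cnvs`, `gene_intervals`, `categories`,
#'   `genes`, `truth`) and, if written, `paths`.
#' @export
#' @examples
#' sim <- simulate_inputs(sim_config(seed = 1, n_genes = 30, n_cases = 50))
simulate_inputs <- function(cfg, dir = NULL) {
  ppi <- simulate_ppi(cfg)
  cohort <- simulate_cohort(cfg, ppi$truth)
  ann <- simulate_annotations(cohort$truth, cfg)
  ont <- simulate_ontology_and_calls(ann$truth, cfg)
  xr <- simulate_crossref(ont$truth, cfg)
  truth <- xr$truth
  genes <- names(truth$community_of_gene)

  out <- list(
    edges = ppi$edges, cohort = cohort, gene_sets = ann$gene_sets,
    dag = ont$dag, calls = ont$calls,
    denovo = xr$denovo, cnvs = xr$cnvs, gene_intervals = xr$gene_intervals,
    categories = xr$categories, genes = genes, truth = truth
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    readr::write_tsv(ppi$edges, p("ppi_edges.tsv"))
    write_cohort_vcf(cohort, p("cohort.vcf"))
    write_control_af(cohort$control_af, p("control_af.tsv"))
    readr::write_lines(genes, p("genes.txt"))
    write_gmt(ann$gene_sets, p("pathways.gmt"))
    readr::write_tsv(ont$dag, p("ontology.tsv"))
    readr::write_tsv(ont$calls, p("expression_calls.tsv"))
    readr::write_tsv(xr$denovo, p("denovo.tsv"))
    readr::write_tsv(xr$cnvs, p("cnvs.tsv"))
    readr::write_tsv(xr$gene_intervals, p("gene_intervals.tsv"))
    readr::write_tsv(xr$categories, p("categories.tsv"))
    yaml::write_yaml(truth_to_list(truth), p("truth.yaml"))
    out$paths <- setNames(
      file.path(dir, c(
        "ppi_edges.tsv", "cohort.vcf", "control_af.tsv", "genes.txt",
        "pathways.gmt", "ontology.tsv", "expression_calls.tsv", "denovo.tsv",
        "cnvs.tsv", "gene_intervals.tsv", "categories.tsv", "truth.yaml"
      )),
      c("edges", "vcf", "control_af", "genes", "gmt", "ontology", "calls",
        "denovo", "cnvs", "gene_intervals", "categories", "truth")
    )
  }
  out
}

truth_to_list <- function(truth) {
  list(
    community_of_gene = as.list(truth$community_of_gene),
    enriched_pathway_of_community = as.list(truth$enriched_pathway_of_community),
    enriched_region_of_community = as.list(truth$enriched_region_of_community),
    carrier_cases_by_gene = truth$carrier_cases_by_gene,
    qualifying_keys = truth$qualifying$key,
    crossref = truth$crossref
  )
}

#' Read a candidate gene list (one symbol per line)
#'
#' @param path Text file path.
#' @return Character vector of gene symbols (whitespace-stripped, blank lines
#'   dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a control allele-frequency table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return Tibble keyed by `chrom:pos:ref:alt`.
#' @export
read_control_af <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", af = "d"
  ), comment = "#") |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
}
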