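#' Pipeline configuration
#'
#' Collects every path and tuning parameter of the end-to-end analysis. When
#' `simulate` is `TRUE` the synthetic generator writes all inputs into
#' `input_dir` first; otherwise the named input files must already exist
#' there (file names as produced by [simulate_inputs()], overridable through
#' `files`). The effective configuration is serialised alongside the outputs
#' for provenance, and every output table carries a config hash.
#'
#' @param input_dir Directory holding (or receiving) the pipeline inputs.
#' @param out_dir Directory for outputs.
#' @param simulate Generate synthetic inputs first?
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param qc A [qc_thresholds()].
#' @param confidence_min Edge confidence cutoff for [build_network()].
#' @param community A [quality_config()] for [leiden_communities()].
#' @param universe Enrichment universe mode: `"annotation"` (union of all
#'   genes in the gene-set collection) or `"network"` (network genes only).
#' @param parent_child Parent-child universe variant (`"union"` or
#'   `"intersection"`).
#' @param alpha Significance level for pathway enrichment.
#' @param q_threshold Display threshold for region Q-values.
#' @param files Named list of file-name overrides (keys as in
#'   [simulate_inputs()] paths).
#' @return A list of class `ns_pipeline_config`.
#' @export
ns_config <- function(input_dir, out_dir,
                      simulate = FALSE,
                      sim = sim_config(),
                      qc = qc_thresholds(),
                      confidence_min = 0.4,
                      community = quality_config(),
                      universe = c("annotation", "network"),
                      parent_child = c("union", "intersection"),
                      alpha = 0.05,
                      q_threshold = 0.05,
                      files = list()) {
  universe <- match.arg(universe)
  parent_child <- match.arg(parent_child)
  default_files <- list(
    edges = "ppi_edges.tsv", vcf = "cohort.vcf", control_af = "control_af.tsv",
    genes = "genes.txt", gmt = "pathways.gmt", ontology = "ontology.tsv",
    calls = "expression_calls.tsv", denovo = "denovo.tsv", cnvs = "cnvs.tsv",
    gene_intervals = "gene_intervals.tsv", categories = "categories.tsv"
  )
  files <- modifyList(default_files, files)
  structure(
    list(
      input_dir = input_dir, out_dir = out_dir, simulate = simulate,
      sim = sim, qc = qc, confidence_min = confidence_min,
      community = community, universe = universe,
      parent_child = parent_child, alpha = alpha,
      q_threshold = q_threshold, files = files
    ),
    class = "ns_pipeline_config"
  )
}

# hash of the analysis parameters (paths excluded, so the same analysis in a
# different directory carries the same provenance hash)
config_hash <- function(config) {
  keep <- setdiff(names(config), c("input_dir", "out_dir"))
  rlang::hash(config_to_list(config[keep]))
}

config_to_list <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

write_stage_tsv <- function(df, path, hash) {
  readr::write_lines(sprintf("# nsnet config %s", hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate (optional), variant
#' filtering, network construction, Leiden community detection, pathway
#' enrichment, brain-region expression enrichment, cross-dataset validation,
#' report — writing each stage's table to `out_dir` as TSV (with a header and
#' the config hash) plus a GraphML network, the effective config and a
#' human-readable report. A stage failure aborts with the failing stage
#' named. Fixed config and seed give byte-identical output tables.
#'
#' @param config An [ns_config()].
#' @return Invisibly, a list with all in-memory stage results (`qv`,
#'   `summary`, `burden`, `network`, `net_summary`, `partition`,
#'   `community_stats`, `enrichment`, `regions`, `region_order`, `evidence`,
#'   `report`, `paths`).
#' @export
run_ns_pipeline <- function(config) {
  stopifnot(inherits(config, "ns_pipeline_config"))
  hash <- config_hash(config)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  inp <- function(key) file.path(config$input_dir, config$files[[key]])
  outp <- function(f) file.path(config$out_dir, f)

  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      stop_nsnet("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (config$simulate) {
    stage("simulate", simulate_inputs(config$sim, config$input_dir))
  }
  missing <- purrr::keep(names(config$files), ~ !file.exists(inp(.x)))
  if (length(missing) > 0) {
    stop_nsnet("missing input file(s): %s",
               paste(map_chr(missing, inp), collapse = ", "))
  }

  ## variant filtering ------------------------------------------------------
  res <- list()
  stage("filter", {
    vcf <- read_cohort_vcf(inp("vcf"))
    control <- read_control_af(inp("control_af"))
    genes <- read_gene_list(inp("genes"))
    res$qv <- qualifying_variants(vcf, control, genes, config$qc)
    res$summary <- summarize_cohort(res$qv, length(vcf$samples), length(genes))
    res$burden <- per_gene_burden(res$qv, length(vcf$samples))
  })

  ## network ----------------------------------------------------------------
  stage("network", {
    edges <- readr::read_tsv(inp("edges"), col_types = readr::cols(
      geneA = "c", geneB = "c", confidence = "d"
    ), comment = "#")
    res$network <- build_network(edges, unique(res$qv$gene), config$confidence_min)
    res$net_summary <- network_summary(res$network)
  })

  ## communities ------------------------------------------------------------
  stage("communities", {
    res$partition <- leiden_communities(res$network, config$community)
    res$community_stats <- community_case_stats(res$partition, res$qv)
  })

  ## pathway enrichment -----------------------------------------------------
  stage("enrich", {
    sets <- read_gmt(inp("gmt"))
    universe <- if (config$universe == "annotation") {
      union(unlist(sets), names(res$partition$membership))
    } else {
      names(res$partition$membership)
    }
    res$enrichment <- enrich_communities(res$partition, sets,
                                          universe = universe,
                                          alpha = config$alpha)
  })

  ## brain-region expression ------------------------------------------------
  stage("express", {
    dag <- read_ontology(inp("ontology"))
    calls <- read_expression_calls(inp("calls"))
    res$regions <- suppressWarnings(
      region_enrichment(res$partition, dag, calls,
                        variant = config$parent_child,
                        q_threshold = config$q_threshold)
    )
    res$region_order <- if (ncol(res$regions$q) >= 2) {
      cluster_communities(res$regions)
    } else {
      list(order = colnames(res$regions$q), tree = NULL)
    }
  })

  ## cross-dataset validation -----------------------------------------------
  stage("crossref", {
    denovo <- readr::read_tsv(inp("denovo"), col_types = readr::cols(
      gene = "c", maf = "d", sift = "c", polyphen = "c"
    ), comment = "#")
    cnvs <- readr::read_tsv(inp("cnvs"), col_types = readr::cols(
      chrom = "c", start = "i", end = "i", de_novo = "l", n_algorithms = "i"
    ), comment = "#")
    iv <- readr::read_tsv(inp("gene_intervals"), col_types = readr::cols(
      gene = "c", chrom = "c", start = "i", end = "i"
    ), comment = "#")
    cats <- readr::read_tsv(inp("categories"), col_types = readr::cols(
      gene = "c", category = "c"
    ), comment = "#")
    res$evidence <- tally_evidence(
      names(res$partition$membership), res$partition,
      filter_denovo(denovo), filter_cnvs(cnvs, iv)$genes,
      select_categories(cats)
    )
  })

  ## outputs ----------------------------------------------------------------
  stage("write", {
    write_stage_tsv(
      res$qv |> mutate(carriers = map_chr(.data$carriers, paste, collapse = ",")),
      outp("qualifying_variants.tsv"), hash
    )
    write_stage_tsv(res$summary |> select(-"sharing"), outp("cohort_summary.tsv"), hash)
    write_stage_tsv(res$summary$sharing[[1]], outp("sharing_histogram.tsv"), hash)
    write_stage_tsv(res$burden, outp("gene_burden.tsv"), hash)
    write_network(res$network, graphml = outp("network.graphml"))
    write_stage_tsv(write_network(res$network), outp("network_edges.tsv"), hash)
    write_stage_tsv(tidy(res$partition), outp("partition.tsv"), hash)
    write_stage_tsv(res$community_stats, outp("community_stats.tsv"), hash)
    write_stage_tsv(res$enrichment, outp("enrichment.tsv"), hash)
    write_stage_tsv(
      res$regions$long |> pivot_wider(id_cols = "term", names_from = "community",
                                      values_from = "q"),
      outp("region_q.tsv"), hash
    )
    write_stage_tsv(res$evidence$per_gene, outp("evidence_per_gene.tsv"), hash)
    write_stage_tsv(res$evidence$per_community, outp("evidence_per_community.tsv"), hash)
    yaml::write_yaml(config_to_list(config), outp("config.yaml"))
  })

  res$report <- ns_report(res, path = outp("report.md"))
  out_files <- c(
    "qualifying_variants.tsv", "cohort_summary.tsv", "sharing_histogram.tsv",
    "gene_burden.tsv", "network_edges.tsv", "network.graphml", "partition.tsv",
    "community_stats.tsv", "enrichment.tsv", "region_q.tsv",
    "evidence_per_gene.tsv", "evidence_per_community.tsv", "config.yaml",
    "report.md"
  )
  res$paths <- setNames(outp(out_files), out_files)
  invisible(res)
}

#' Assemble a human-readable pipeline report
#'
#' Builds a markdown summary of the stage outputs: cohort and filter counts,
#' network statistics, community table with top pathway enrichment, the most
#' enriched brain region per community and the validation tallies. Missing
#' stages yield a partial report with warnings.
#'
#' @param results Stage results from [run_ns_pipeline()] (any subset).
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is given.
#' @export
ns_report <- function(results, path = NULL) {
  lines <- c("# Rare-variant interaction-network community report", "")
  if (!is.null(results$summary)) {
    s <- results$summary
    lines <- c(lines, "## Cohort", sprintf(
      "- %d qualifying variants in %d genes (%d%% of %d candidates); %d carrier cases (%d%% of %d); %d private variants",
      s$n_variants, s$n_genes, s$pct_genes, s$n_candidate_genes,
      s$n_carrier_cases, s$pct_cases, s$n_cohort, s$n_private
    ), "")
  } else {
    warn("ns_report: cohort summary missing")
    lines <- c(lines, "## Cohort", "- (missing)", "")
  }
  if (!is.null(results$summary) && results$summary$n_variants == 0) {
    lines <- c(lines, "Note: zero qualifying variants survived the filters.", "")
  }
  if (!is.null(results$net_summary)) {
    ns <- results$net_summary
    lines <- c(lines, "## Network", sprintf(
      "- %d nodes, %d edges, average local clustering %.3f",
      ns$n_nodes, ns$n_edges, ns$avg_clustering
    ), "")
  }
  if (!is.null(results$partition)) {
    g <- glance(results$partition)
    lines <- c(lines, "## Communities", sprintf(
      "- %d communities, %s = %.4f after %d passes",
      g$n_communities, g$quality_fn, g$quality, g$passes
    ))
    if (!is.null(results$community_stats)) {
      st <- results$community_stats
      top <- if (!is.null(results$enrichment)) {
        results$enrichment |> slice_min(.data$p_adj, n = 1, by = "community",
                                        with_ties = FALSE)
      } else {
        NULL
      }
      for (i in seq_len(nrow(st))) {
        lab <- if (!is.null(top)) {
          t1 <- top[top$community == st$community[i], ]
          if (nrow(t1) == 1) {
            sprintf("; top set %s (fold %.1f, q = %.2g)", t1$set, t1$fold, t1$p_adj)
          } else {
            ""
          }
        } else {
          ""
        }
        lines <- c(lines, sprintf(
          "- community %d: %d genes, %d variants, %d cases (%.1f%% of network cases)%s",
          st$community[i], st$n_genes[i], st$n_variants[i], st$n_cases[i],
          st$pct_of_network_cases[i], lab
        ))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$regions)) {
    r <- results$regions
    best <- r$long |> slice_min(.data$q, n = 1, by = "community", with_ties = FALSE)
    lines <- c(lines, "## Brain-region enrichment", sprintf(
      "- %d region(s) with Q < %g", length(r$significant_terms), r$q_threshold
    ), sprintf("- community %s: most enriched region %s (Q = %.2g)",
               best$community, best$term, best$q), "")
  }
  if (!is.null(results$evidence)) {
    pc <- results$evidence$per_community
    lines <- c(lines, "## Cross-dataset validation", sprintf(
      "- %d network gene(s) with any prior evidence (de novo SNV %d, CNV %d, category %d)",
      sum(pc$n_any_evidence), sum(pc$n_denovo), sum(pc$n_cnv), sum(pc$n_category)
    ), "")
  }
  if (!is.null(path)) {
    readr::write_lines(lines, path)
    return(invisible(lines))
  }
  lines
}
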