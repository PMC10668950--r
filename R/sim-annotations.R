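#' Simulate pathway gene sets (GMT) with one planted set per community
#'
#' For each planted community one gene set is created whose members are drawn
#' from that community with probability `pathway_purity` (and uniformly from
#' the remaining genes otherwise); the other `n_pathways - n_communities`
#' sets are uniform decoys. Set names are shuffled so nothing about planting
#' is visible to the enrichment stage; the mapping community -> planted set
#' name is recorded in the truth.
#'
#' @param truth Planted truth from [simulate_ppi()].
#' @param cfg A [sim_config()].
#' @return A list with `gene_sets` (named list of gene symbol vectors) and the
#'   updated `truth` (slot `enriched_pathway_of_community`).
#' @export
simulate_annotations <- function(truth, cfg) {
  stopifnot(inherits(cfg, "ns_sim_config"), inherits(truth, "ns_planted_truth"))
  comm <- truth$community_of_gene
  genes <- names(comm)
  k <- cfg$n_communities
  if (cfg$n_pathways < k) {
    stop_nsnet("n_pathways must be at least n_communities")
  }

  with_seed(cfg$seed + 2L, {
    size_range <- 15:25
    planted <- lapply(seq_len(k), function(c) {
      members_in <- genes[comm == c]
      s <- sample(size_range, 1)
      if (cfg$pathway_purity >= 1) s <- min(s, length(members_in))
      from_comm <- runif(s) < cfg$pathway_purity
      n_in <- min(sum(from_comm), length(members_in))
      inside <- sample(members_in, n_in)
      outside_pool <- setdiff(genes, inside)
      outside <- sample(outside_pool, min(s - n_in, length(outside_pool)))
      sort(unique(c(inside, outside)))
    })
    decoys <- lapply(seq_len(cfg$n_pathways - k), function(i) {
      sort(sample(genes, sample(size_range, 1)))
    })
    sets <- c(planted, decoys)
    nm <- sprintf("PW%03d", seq_along(sets))
    ord <- sample(seq_along(sets))
    gene_sets <- setNames(sets[ord], nm)
    planted_names <- nm[match(seq_len(k), ord)]
  })

  truth$enriched_pathway_of_community <- setNames(planted_names, seq_len(k))
  list(gene_sets = gene_sets, truth = truth)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of gene symbol vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of gene symbol vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- map_chr(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
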