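#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort/network/annotation generator.
#' The defaults define the reference simulation conditions used throughout the
#' package: a planted-partition interaction network that is clearly
#' recoverable (`p_in` well above `p_out`), a cohort in which a little over
#' half of the genes carry a qualifying loss-of-function variant, one planted
#' pathway and one planted brain region per community, and contaminant
#' variant sites that each violate exactly one filter.
#'
#' @param seed Integer seed; all stochastic draws flow from it, so a fixed
#'   config yields byte-identical output files.
#' @param n_genes Number of candidate genes (symbols `G0001`, ...).
#' @param n_communities Number of planted communities.
#' @param p_in,p_out Within/between-community edge probabilities; recovery
#'   requires `p_in > p_out`.
#' @param n_cases Number of sequenced cases in the synthetic cohort.
#' @param n_controls_freq_table Nominal control count behind the allele
#'   frequency table (denominator used when reporting frequencies).
#' @param lof_rate_per_gene Probability that a gene carries a planted
#'   qualifying loss-of-function site.
#' @param background_variant_rate Probability that a gene additionally carries
#'   a non-LoF ("other" consequence) site, which must be removed by the
#'   consequence filter.
#' @param frac_common_contaminant Fraction of emitted LoF sites planted with a
#'   control allele frequency of at least 0.1%, which must be removed by the
#'   population-frequency filter.
#' @param n_pathways Total number of gene sets in the synthetic GMT (one
#'   planted set per community, the rest uniform decoys).
#' @param pathway_purity Fraction of each planted pathway drawn from its
#'   community's genes.
#' @param n_regions Number of brain regions (children of the root "brain"
#'   term) in the synthetic anatomy ontology.
#' @param region_signal_strength Odds multiplier for the planted
#'   region-community expression association; 1 means no planted signal.
#' @return A list of class `ns_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 60, n_communities = 3)
sim_config <- function(seed = 1L,
                       n_genes = 150L,
                       n_communities = 5L,
                       p_in = 0.3,
                       p_out = 0.02,
                       n_cases = 400L,
                       n_controls_freq_table = 60146L,
                       lof_rate_per_gene = 0.6,
                       background_variant_rate = 0.3,
                       frac_common_contaminant = 0.15,
                       n_pathways = 25L,
                       pathway_purity = 0.9,
                       n_regions = 10L,
                       region_signal_strength = 20) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_communities = as.integer(n_communities),
    p_in = p_in, p_out = p_out,
    n_cases = as.integer(n_cases),
    n_controls_freq_table = as.integer(n_controls_freq_table),
    lof_rate_per_gene = lof_rate_per_gene,
    background_variant_rate = background_variant_rate,
    frac_common_contaminant = frac_common_contaminant,
    n_pathways = as.integer(n_pathways),
    pathway_purity = pathway_purity,
    n_regions = as.integer(n_regions),
    region_signal_strength = region_signal_strength
  )
  probs <- c(
    p_in = p_in, p_out = p_out,
    lof_rate_per_gene = lof_rate_per_gene,
    background_variant_rate = background_variant_rate,
    frac_common_contaminant = frac_common_contaminant,
    pathway_purity = pathway_purity
  )
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0) {
    stop_nsnet("sim_config: probabilities out of [0,1]: %s",
               paste(bad, collapse = ", "))
  }
  if (cfg$n_genes < cfg$n_communities || cfg$n_communities < 1) {
    stop_nsnet("sim_config: need n_genes >= n_communities >= 1")
  }
  if (cfg$n_regions < 2) {
    stop_nsnet("sim_config: need n_regions >= 2")
  }
  if (region_signal_strength <= 0) {
    stop_nsnet("sim_config: region_signal_strength must be positive")
  }
  structure(cfg, class = "ns_sim_config")
}

gene_symbols <- function(n) sprintf("G%04d", seq_len(n))

case_ids <- function(n) sprintf("CASE%04d", seq_len(n))
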