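---
title: "Methods: rare-variant interaction networks and community detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant interaction networks and community detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsnet)
```

# Overview

nsnet implements a complete analysis chain for asking which biological
processes are disrupted by ultra-rare loss-of-function (LoF) variation in a
curated set of candidate genes — here motivated by neurotransmission and
synaptic (NS) genes in autism spectrum disorder, but applicable to any
candidate list:

1. **Variant filtering** — from a cohort VCF, keep variants that pass
   genotype/site quality control, are ultra-rare in a large control
   population, have a LoF consequence, and fall in the candidate list.
2. **Network construction** — span a confidence-weighted protein–protein
   interaction (PPI) network over the genes hit by qualifying variants.
3. **Community detection** — decompose the network into biological
   communities with a from-scratch Leiden algorithm driven by weighted
   modularity.
4. **Community characterisation** — pathway overrepresentation per
   community, brain-region expression enrichment over a `part_of` anatomy
   ontology with parent–child decorrelation, and cross-referencing against
   independent evidence (de novo SNVs, de novo CNVs, curated gene
   categories).

Because the real inputs of such studies (controlled-access cohorts, live
interaction and expression databases) cannot be redistributed, the package
ships a synthetic-data generator that emulates every input with planted
ground truth, so the full chain is testable offline.

# Variant filtering

## Model and thresholds

A genotype is a qualifying carrier call when, at a non-reference call,

* read depth `DP > 8` (strict: `DP = 8` fails),
* genotype quality `GQ > 20` (strict),
* allele balance `AD_alt / (AD_ref + AD_alt) > 0.2` (strict).

A site is kept when `VQSLOD >= -1.5` (non-strict) and the fraction of
missing genotypes among cases is `< 10%` (strict). A variant qualifies when
the site passes, at least one carrier genotype passes, its control
minor-allele frequency is `< 0.1%` (strict; sites absent from the control
table count as frequency 0 — absence from a large control cohort is the
strongest rarity evidence available), its consequence is one of the five
LoF classes (frameshift, stop gain, start lost, splice acceptor, splice
donor), and its gene is on the candidate list.

Design choices worth flagging:

* The allele-balance reading of the `AD > 0.2` threshold: a raw allelic
  depth of 0.2 reads would be vacuous, so the threshold is applied to the
  alt-read *fraction*, and only at genotypes carrying the ALT allele.
* Missingness is computed over cases only; whether controls should enter
  the denominator is ambiguous in common practice, and cases-only is the
  conservative choice for a case-only burden table.
* MAF is `min(AF, 1 - AF)` of the ALT allele; for genuinely ultra-rare
  sites AF and MAF coincide.
* Multiallelic records must be pre-split; the reader rejects multi-ALT rows
  with the offending line number rather than guessing an allele.
* Coordinates are 1-based inclusive (VCF convention) throughout.
* Printed percentages round half away from zero — integer at cohort level,
  one decimal for per-gene tables — matching how such counts are usually
  typeset, and `round_half_away()` makes the convention explicit rather
  than inheriting banker's rounding.

`summarize_cohort()` and `per_gene_burden()` reproduce the usual headline
arithmetic (percent of cases carrying a qualifying variant, percent of
candidate genes hit, per-gene carrier percentages, the sharing histogram
and private-variant count). A case carrying several variants in one gene
counts once for that gene.

# Network construction

`build_network()` keeps edges with both endpoints among the qualifying
genes and confidence at least `confidence_min` (default 0.4, the
conventional "medium confidence" cutoff for STRING-style combined scores;
the threshold is configurable precisely because published analyses often
leave it unstated). Qualifying genes without surviving edges stay in the
network as degree-0 nodes: every qualifying gene carries cases, so dropping
isolated genes would silently change case accounting downstream. Edge
confidences act as weights everywhere; unweighted analysis is the special
case of unit weights.

`network_summary()` reports node/edge counts, per-node degree and the
average local clustering coefficient, with nodes of degree < 2 contributing
0 (the convention that keeps the average defined on sparse graphs).

# Leiden community detection

The community stage is implemented from scratch (no call into an external
community-detection library) as the three classic phases, iterated until a
pass makes no move:

1. **Local moving** with a work queue: nodes are visited in a seeded random
   order; a node moves to the neighbouring community with the largest
   quality gain (an empty community is always a candidate, so isolation
   moves are possible); when a node moves, its neighbours outside the new
   community re-enter the queue. Ties in gain break toward the smallest
   community label, which keeps runs reproducible at a fixed seed.
2. **Refinement**: within each community, starting from singletons, nodes
   merge into connected sub-communities with probability proportional to
   `exp(gain / theta)` among non-degrading candidates (`theta = 0.01`).
   Refinement is what guarantees communities induce connected subgraphs.
3. **Aggregation** by the refined partition, conserving total edge weight
   (intra-community weight becomes self-loop weight), with the previous
   community assignment carried over as the starting partition.

Quality functions: weighted Newman–Girvan modularity
`Q = sum_c [ w_c / W - gamma (s_c / 2W)^2 ]` (default, `gamma = 1`), and the
constant Potts model `H = sum_c [ w_c - gamma n_c (n_c - 1) / 2 ]` for
resolution-limit-free sensitivity runs. The number of communities is an
output of the optimisation, never a parameter.

Numerical and design choices:

* **Restarts.** Greedy local moving can stall in a shallow local optimum on
  small graphs. `leiden_communities()` therefore runs `n_restarts = 5`
  independent seeded runs — the first from singletons, later ones from a
  random coarse initial partition — and keeps the best-quality result. On
  exhaustive-search comparisons (all partitions of graphs with up to 8
  nodes) this attains the global modularity optimum in essentially all
  random instances, which single-start greedy moving does not.
* **Connectedness safety net.** After convergence any community that fails
  to induce a connected subgraph is split into its components; for
  modularity this never decreases quality (the degree-sum penalty is
  convex), and degree-0 genes end as singleton communities by construction.
* **Determinism.** All randomness flows from the config seed; a fixed seed
  gives an identical partition. Quality is non-decreasing across passes and
  is asserted as such in the tests.
* **Labels.** Final labels are contiguous `0..k-1`, ordered by decreasing
  community size with ties broken by the smallest member symbol.

`community_case_stats()` counts, per community, genes, qualifying variants
and distinct carrier cases; a case counts toward every community where it
carries a qualifying variant, and percentages are taken against the
distinct cases across the whole network.

# Pathway overrepresentation

`enrich_communities()` performs one-sided hypergeometric (Fisher exact
upper-tail) overrepresentation of each community against a GMT collection:
`p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` and fold enrichment
`(k/n) / (K/N)`. The default universe is the union of all genes in the
annotation collection (standard ORA practice; a "network genes only"
universe is selectable), and Benjamini–Hochberg adjustment is applied
within each community's family of tested sets, matching the per-panel
presentation such results usually get. Only non-empty overlaps are
reported. The test choice follows the defaults of the common enrichment
tool family; published analyses typically name the tool rather than the
test.

# Brain-region expression enrichment

Expression calls are first propagated up the `part_of` anatomy DAG
(true-path rule: present at a term implies present at every ancestor).
For each non-root term, the **parent–child union** test conditions the
term's enrichment on its parents: the sampling universe is the set of genes
annotated (after propagation) to the union of the term's parents, successes
are the genes annotated to the term itself, and draws are the community
genes inside that universe. On a flat ontology this reduces exactly to the
plain hypergeometric against the root universe — a property the tests
exploit as an oracle. The intersection variant is available by flag; union
is the common default in topGO-derived implementations, and the exact
variant used by published expression-enrichment services is generally not
pinned down, so the choice is documented here rather than claimed
identical.

Per community, p-values over all terms are BH-adjusted to Q-values; rows
(regions) with any `Q < 0.05` form the display set, and
`cluster_communities()` orders columns by average-linkage hierarchical
clustering of the Euclidean distances between `-log10(Q)` profiles, so the
heatmap groups communities with similar regional specificity. A term with
no parent-annotated genes gets `p = 1` with a warning; a community with no
expressed genes yields a column of ones.

# Cross-dataset validation

Three independent evidence channels are filtered with explicit rules:

* de novo SNVs qualify at population MAF `< 0.001` (strict) with a damaging
  SIFT **or** PolyPhen label; "possibly damaging" counts as damaging, since
  the usual reporting ("deleterious and/or damaging") does not grade.
* de novo CNVs qualify when flagged de novo and detected by at least two
  algorithms; a gene is hit at >= 1 bp overlap between closed 1-based
  intervals, so a CNV ending exactly at a gene's start touches it. No
  reciprocal-overlap rule is applied; the overlap convention is a
  documented choice.
* category entries qualify at score 1 or 2 or with the syndromic flag
  ("2S" qualifies on both grounds, "3S" via the flag, plain "3" not).

`tally_evidence()` reports per-gene boolean flags plus a union flag (a gene
counts once however many sources support it) and per-community sums, so the
union count is reported alongside the per-source counts rather than picking
one deduplication order.

# The synthetic-data generator

`simulate_inputs()` generates every input the pipeline reads, with planted
truth recorded alongside:

* **Network**: a planted-partition graph (`p_in = 0.3` within blocks,
  `p_out = 0.02` between; `n_genes = 150` in 5 equal communities).
  Within-community confidences are drawn from U(0.60, 0.98),
  between-community from U(0.15, 0.55), emulating the tendency of
  interaction scores to be higher inside functional modules. These defaults
  put the simulation in a clearly recoverable regime at a scale comparable
  to a real candidate-gene network (a few dozen genes per community).
* **Cohort**: 400 cases; each gene carries a planted qualifying LoF site
  with probability 0.6 (plus a small Poisson excess of extra sites), with
  1–3 carriers so most variants are private. Contaminant sites each violate
  exactly one filter: low VQSLOD, high missingness, carrier DP/GQ/allele
  balance failures, control AF >= 0.1%, non-LoF consequence, or an off-list
  gene. The control table contains all common contaminants plus a random
  30% of the remaining sites at frequencies of a few alleles in 60,146
  controls, so both "absent" and "present but ultra-rare" paths are
  exercised.
* **Pathways**: one planted set per community drawn at purity 0.9 (sizes
  15–25) plus uniform decoys, to 25 sets total; names are shuffled so
  nothing marks the planted set.
* **Ontology and calls**: a flat two-level `part_of` ontology ("brain" with
  10 region children — matching the children-of-root selection used with
  real anatomy ontologies; deeper fixtures are used in tests). Baseline
  presence probability is 0.3; genes of community *c* in that community's
  planted region have their presence odds multiplied by 20 (presence
  probability ~0.90), a strong regional-specificity signal.
* **Cross-reference tables**: records planted to pass and to fail each
  validation rule, plus synthetic gene intervals for CNV overlap.

A fixed `sim_config()` (including its seed) produces byte-identical files;
generator streams are decoupled by fixed seed offsets per stage, so using
the cohort does not perturb the ontology draws.

What the generator deliberately does **not** emulate: linkage
disequilibrium and realistic mutation-rate variation, sequence context,
trio structure and inheritance, hub-dominated (scale-free) PPI degree
distributions, overlapping pathways with hierarchical structure, or
correlated expression across adjacent brain regions. Passing the planted
recovery suite therefore demonstrates that the machinery is correct and
well-calibrated in a favourable regime, not that the pipeline would recover
weak signals from real cohorts.

## Reference problem sizes

The test and acceptance runs use: exhaustive-search comparisons on 100
random graphs of 5–8 nodes (all set partitions enumerated, Bell(8) = 4140);
planted-community recovery on 60-node, 3-block networks over 20 seeds
(scored as normalised mutual information, NMI >= 0.9); and 20 end-to-end
synthetic runs at the default 150-gene configuration, scoring, for every
recovered community (matched to its majority planted block), whether the
planted pathway ranks first and the planted region attains the
column-minimum Q. The per-community pooled rates are the reported
quantities; with five communities per run, requiring every community of
every run to succeed would compound independent events into a much stricter
criterion than the per-recovery rate of interest.

# Known limitations

* The Leiden implementation is pure R; it is comfortable at the hundreds-
  of-nodes scale this analysis needs, and exact on small graphs, but it is
  not tuned for networks of 10^5+ nodes.
* Pathway enrichment treats gene sets as flat; no term-graph redundancy
  reduction is applied to pathway collections (the anatomy stage does
  condition on parents).
* The carrier model assumes a single ALT allele per record and does not
  phase compound heterozygotes.
* Q-values are BH-adjusted p-values; no empirical-null or pi0 estimation is
  attempted.
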