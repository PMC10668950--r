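Package: nsnet
Title: Rare-Variant Protein Interaction Networks and Community Detection
    for Neurotransmission and Synaptic Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mapping ultra-rare loss-of-function
    variants in neurotransmission and synaptic candidate genes onto a
    weighted protein-protein interaction network, decomposing the network
    into biological communities with a from-scratch Leiden algorithm, and
    characterising communities by pathway overrepresentation, brain-region
    expression enrichment over a part_of anatomy ontology with parent-child
    decorrelation, and cross-dataset validation evidence (de novo SNVs,
    de novo CNVs, curated candidate-gene categories). Includes a synthetic
    data generator with planted community structure, planted rare-variant
    burden, planted pathway enrichment and planted regional expression
    signal, so that every stage is testable without access to controlled
    cohort data or live databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
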