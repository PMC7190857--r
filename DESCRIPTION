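Package: mirsitevar
Title: Variants Disrupting miRNA Binding Sites in Obesity and Diabetes Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying single-nucleotide variants
    that fall inside consensus-predicted miRNA binding sites in 3'UTRs,
    linking the affected genes to tissue-specific up-regulation, obesity and
    diabetes QTL, cross-species (mouse to human) seed conservation, and
    knockout/GWAS/eQTL phenotype evidence. Includes consensus voting over
    multiple target-prediction tools, interval-based variant/site
    intersection, contingency-table and hypergeometric enrichment statistics
    with Benjamini-Hochberg correction, Smith-Waterman alignment of mature
    miRNAs for seed-conservation calls, regulatory network assembly, and a
    synthetic-data generator with a truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
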