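Package: mgorder
Title: Quantitative Analysis of Mitochondrial Gene-Order Rearrangement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the architectural evolution of
    mitochondrial genomes from annotated gene orders. Standardizes
    annotated mitogenomes into canonical circular, strand-aware gene
    orders; detects control regions from intergenic gaps and validates
    annotations; deduplicates samples into gene-order types; quantifies
    rearrangement per gene (RF) and per genome (RS) under an
    alignment-free neighbor scheme and a breakpoint-partitioned aligned
    scheme; reconstructs ancestral gene-order types on time-calibrated
    phylogenies by parsimony; accumulates rearrangement scores in fixed
    time slices into cumulative curves; relates per-family species
    richness to rearrangement load with local regression; and simulates
    gene-order evolution along trees with ground-truth event logs for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
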