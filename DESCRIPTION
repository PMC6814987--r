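Package: mitodecay
Title: Comparative Analysis of Plant Mitochondrial Genomes: Repeats,
    Shared DNA Decay and Horizontal Transfer
Version: 0.1.0
Authors@R:
    person("Mito", "Decay", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for comparative analysis of plant mitochondrial
    genomes (mitogenomes). Provides a self-contained seed-and-extend local
    aligner with Karlin-Altschul significance statistics, dispersed and
    tandem repeat annotation with repetitive/single-copy partitioning,
    large-repeat collapsing, pairwise shared-DNA estimation and its decay
    against Kimura two-parameter (K2P) coding-sequence distance,
    plastid-derived insertion (MIPT) detection, horizontal-transfer donor
    profiling for parasitic plants, classification of the ancestral
    mitochondrial protein-coding gene set, and a genome-evolution
    simulator that emits ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
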