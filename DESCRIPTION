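Package: contamScreen
Title: Reference-Free Contamination Screening for Bacterial Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reference-free quality-control and contamination-screening
    pipeline for bacterial next-generation sequencing data. Reads are quality
    trimmed, assembled into contigs with a built-in de Bruijn unitig
    assembler, binned into species-level clusters from tetranucleotide
    composition and read coverage with a Gaussian mixture model, target
    clusters are identified from a handful of species-specific marker genes,
    and target reads are rescued by mapping back to target contigs. A
    synthetic contaminated-community simulator with full ground truth makes
    every stage testable without reference databases, and an evaluation
    module scores runs with cluster purity, target concentration,
    sensitivity/specificity, per-stage data loss, and base- and gene-level
    genome coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, QualityControl, Metagenomics, Clustering, Assembly
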