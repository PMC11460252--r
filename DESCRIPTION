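Package: ssvseqr
Title: Contamination Decomposition of rAAV Vector Preparations from
    Single-Stranded Virus Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the DNA species present in recombinant
    adeno-associated virus (rAAV) vector preparations from single-stranded
    virus sequencing (SSV-seq) read data. Builds a priority-ordered,
    homology-masked multi-species reference panel, competitively classifies
    UMI-tagged paired-end reads against it, and reports per-species
    percentage profiles, normalized coverage and aggregated single-nucleotide
    variants over the vector genome, and intra- versus extra-capsid
    localization of contaminants from paired DNase-treated and untreated
    profiles. Includes a synthetic-data generator with known ground truth
    (reference construction with deliberate cross-species homology, prep
    composition, encapsidation/DNase model, read simulation with UMIs) and
    downstream phenotype analysis of transduced hematopoietic stem and
    progenitor cells: colony-forming-unit clonogenicity, purity-clonogenicity
    regression, and delta-delta-Ct expression fold changes.
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
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
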