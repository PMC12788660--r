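Package: peakTE
Title: Population Discovery of Polymorphic Transposable-Element Families
    from Insertion-Call VCFs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers polymorphic transposable-element (TE) families in a
    population from per-sample insertion-call VCFs. Pools insertion sizes
    across samples and detects enriched size intervals ("peaks") against a
    rolling local-quantile background, clusters the inserted sequences
    within each peak by percent identity to resolve subfamilies, annotates
    representatives against a consensus library, merges insertions across
    samples into population loci with per-group allele frequencies and
    gene-feature annotation, and reconstructs solo-LTR and full-length
    endogenous retrovirus insertions. Includes a synthetic-population
    generator so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
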