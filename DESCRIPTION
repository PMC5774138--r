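Package: crestmir
Title: Small RNA-Seq Analysis of miRNA Hairpins, IsomiRs and Arm Switching
    in Embryonic Explants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiling of microRNAs from small RNA sequencing libraries
    built with high-definition (HD) degenerate adapters, of the kind used
    to characterise Xenopus neural crest, neural, ectoderm and blastula
    explants. Implements HD adapter trimming and read collapsing, exact
    both-strand genome mapping, homology-based hairpin annotation with an
    explicit filter ladder and maximum-base-pairing structure validation,
    isomiR and arm-switch quantification, negative-binomial differential
    expression with Benjamini-Hochberg correction, rule-based novel miRNA
    prediction, density-based detection of 29-nt small RNA clusters, and
    a synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
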