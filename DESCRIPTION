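Package: corebin
Title: Core-Sequence-Based Selection, Refinement and Gap Filling of Metagenomic Bins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-binning curation of metagenome-assembled genomes. Merges
    redundant outputs of multiple binners into hybrid bins, identifies core
    (inlier) contigs from interquartile coverage ranges, removes redundant
    bins by depth-normalized coverage comparison, refines bins by
    multidimensional outlier detection over tetranucleotide frequency and
    coverage-ratio profiles, retrieves un-binned contigs through read-link
    tracking, and closes assembly gaps with a restrained
    overlap-layout-consensus step. Includes a deterministic synthetic
    community generator and a reference-based quality evaluator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    methods,
    nnet,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
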