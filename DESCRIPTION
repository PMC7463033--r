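Package: omamplicon
Title: Reconstruction of Focal Amplifications from Optical Maps and Breakpoint Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs the structure of large focal copy-number
    amplifications (ecDNA, breakage-fusion-bridge, and other complex
    rearrangements) by aligning in-silico digested breakpoint-graph segments
    to optical map contigs. Provides a banded dynamic-programming aligner
    with a label-collapse expectation model and empirical E-value
    significance, scaffold construction with breakpoint-graph gap
    imputation, copy-number-aware path extraction, readers and writers for
    CMAP/XMAP/breakpoint-graph/cycles formats, a simulator for rearranged
    amplicons and noisy consensus optical maps, and longest-common-substring
    precision/recall evaluation of reconstructions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
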