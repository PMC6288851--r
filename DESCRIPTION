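Package: overbin
Title: Reference-Free Metagenomic Read Binning via Exact-Overlap Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bins shotgun metagenomic reads without reference genomes by
    building an overlap graph whose edges link reads sharing an exact common
    substring of at least b bases (forward or reverse complement), filtering
    conserved-region hubs and chimera-suspect reads by degree-histogram
    thresholds, and reporting connected components as per-species bins.
    Includes a ground-truth-labelled synthetic shotgun metagenome generator
    (unequal depths, shared conserved regions, chimeric reads, substitution
    errors), a bin purity/recall evaluator, and a command-line interface for
    the two-pass histogram-then-bin workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
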