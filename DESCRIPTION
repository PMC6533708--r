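Package: brevipan
Title: Pan-Genome Construction and Niche-Association Screens for
    Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative pan-genome analysis of closed bacterial genome
    collections: all-against-all protein similarity with reciprocal
    identity/coverage filtering, in-house Markov clustering into gene
    families, pan/core accumulation curves with power-law and exponential
    fits and an open/closed verdict, presence/absence niche-association
    screens on chromosomes and plasmids, plasmid gene-content sharedness
    classification, genome summary statistics, and single-copy-core
    concatenated supertrees with bootstrap support.  Includes a synthetic
    pan-genome simulator with known family structure so every stage can be
    validated against ground truth, and plain-text fixtures of published
    Lactobacillus brevis genome summaries and beer-spoiler gene tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    igraph,
    Matrix,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
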