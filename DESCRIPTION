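Package: barcodeaudit
Title: Diagnosability Audit of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to audit a COI DNA barcode reference library for
    species-level diagnosability. Computes Kimura-2-parameter distances
    under pairwise deletion, collapses identical haplotypes, classifies
    species into sharing / low-divergence / deep-split categories, scores
    concordance between species and sequence clusters (supplied BIN labels
    or a single-linkage surrogate), re-analyses faunal assemblages by
    ecoregion or latitude/longitude band, quantifies zoogeographic overlap
    and endemism, and runs the associated comparative statistics. Includes
    a seeded synthetic-library generator with planted truth so the whole
    pipeline is testable without external downloads, plus a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
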