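Package: scn3c
Title: Sequential Component Normalization and Bias Analysis for Genomic 3C
    Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing chromosome conformation capture (3C,
    Hi-C-class) data. Builds annotated restriction-fragment maps from genome
    sequences, classifies and filters paired-end ligation products
    (self-loops, religations, adjacent loops, long-range contacts),
    quantifies the three major experimental biases of the protocol
    (restriction-fragment length via a crosslink saturation model, end GC
    content, and DNA circularization length including its helical-twist
    periodicity), and normalizes contact maps with the Sequential Component
    Normalization (SCN) algorithm and its norm-product and marginal-sum
    alternatives, with genomic-distance detrending, correlation maps,
    fragment binning and a visualization blur. A modified ROC procedure
    re-assesses 3D colocalization of genomic feature sets on normalized
    maps. A synthetic-data generator emulates the protocol's event mixture
    and biases with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    yaml
Config/testthat/edition: 3
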