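Package: annocompare
Title: Comparison and Consensus Merging of Bacterial Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two or more structural and functional annotations of the
    same prokaryotic genome supplied as GenBank flat files. Genes are matched
    across annotations by strand-, frame- and coordinate-aware interval
    overlap and classified as identical, similar, unique with overlap or
    unique without overlap; a symmetric similarity score and
    reference-relative false-negative/false-positive reports are computed.
    Multi-annotation clustering yields Venn-style intersection counts and
    extended annotations (EA, EUA and a cleaned EUA) that pool gene-function
    descriptions from all input annotation methods. Includes a synthetic
    GenBank fixture generator with a perturbation truth log, tab-delimited
    and GFF3 exporters, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
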