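Package: siqchip
Title: Sans-Spike-In Quantitative ChIP-Seq (siQ-ChIP)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A physically grounded quantitative scale for ChIP-seq. Computes
    the siQ-ChIP proportionality constant alpha from bench measurements
    (library fractions, PCR cycles, bead-capture yields, IP mass fractions and
    reaction volumes), builds quantitative capture-efficiency genome tracks
    from paired-end fragment intervals, solves the competitive antibody
    binding isotherm to predict IP composition and spike-in sensitivity,
    implements spike-in (histone modification density) normalization
    arithmetic for side-by-side comparison with alpha, provides a
    hypergeometric overlap statistic for coverage tracks, and ships a
    synthetic-data generator with a ground-truth ledger so the whole pipeline
    is testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
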