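Package: fourcseg
Title: Segmentation-Based 4C-seq Interaction Calling and Differential
    Contact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for viewpoint-based chromosome conformation
    capture (4C-seq) data summarised over a functional chromatin
    segmentation. Assigns aligned read intervals to labelled genome
    segments, calls valid viewpoint interactions per replicate by Otsu
    thresholding of log-transformed, 8-bit-scaled segment counts, tests
    differential contacts and differential gene expression with a
    simplified negative-binomial Wald test (median-of-ratios size factors,
    moment dispersion estimates, Benjamini-Hochberg adjustment), annotates
    contacts to gene TSS windows within a topologically associating
    domain, and classifies candidate target genes as repressive,
    activating or neutral contacts. Includes seeded synthetic-data
    generators with planted ground truth for end-to-end validation, and
    helpers for divergent (bidirectional-promoter) gene-pair detection and
    promoter CpG composition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    DESeq2,
    IRanges,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
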