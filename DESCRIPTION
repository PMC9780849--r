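Package: msremeth
Title: Multi-Level Differential DNA Methylation Analysis for MSRE-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for methyl-sensitive restriction enzyme sequencing
    (MSRE-seq) of HpaII (CCGG) sites in two-cohort designs: CCGG site cataloguing
    from a reference genome, per-site methylation scoring from intact-fragment
    read depth, likelihood-ratio differential methylation with Benjamini-Hochberg
    false-discovery-rate control, chromosome-level Fisher enrichment, 1-Mbp
    regional methylation loads with hyper/hypomethylation flagging, and
    TSS-promoter window aggregation. Includes a seeded synthetic-cohort generator
    (negative-binomial coverage linked to per-site methylation probability) with
    planted site, chromosome, block and promoter effects for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    jsonlite,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
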