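Package: castechrom
Title: Differential Chromatin and Expression Analysis for Two-Caste Study Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy reimplementation of a windowed differential histone
    modification ChIP-seq analysis for two-condition (queen vs worker honey
    bee caste) studies. Tiles the genome into overlapping windows, counts
    extended reads, normalizes ChIP signal to expanded-window input coverage,
    calls differential windows with empirical-Bayes moderated t-statistics and
    merges them into regions, places regions in genomic context (TSS distance,
    exon/intron class), tests differential transcript expression with a
    Gaussian likelihood-ratio test, correlates chromatin and expression
    differences, calls differentially methylated positions with Fisher's exact
    test, runs permutation overlap-enrichment tests, and performs PWM central
    motif enrichment on peak-centered sequence windows. Ships a synthetic-data
    generator with a machine-readable truth table so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
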