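Package: silencescan
Title: Maturation-Induced Transcriptional Silencing from Chromatin and
    Nascent-Transcript Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying genes subjected to rapid
    maturation-induced epigenetic silencing in dendritic cells. Calls
    promoter histone-H4 deacetylation from two-channel tiling-array signals,
    classifies transcription-rate changes from chromatin-bound
    nascent-transcript sequencing (RPKM fold-change tiers with an expression
    baseline), intersects the two to obtain the deacetylated-silenced gene
    set, profiles transcription-factor peak occupancy around transcription
    start sites against an all-genes baseline, and tests promoter motif
    enrichment with a Pscan-style z-statistic. Ships a fully deterministic
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
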