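Package: saltdge
Title: Consensus Differential Expression and Alternative Splicing for
    Two-Species Salt-Stress Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a digital gene expression (DGE)
    workflow for comparing the salt-stress transcriptomes of two sister
    species sequenced without biological replicates (one control and one
    salt-stressed library per species).  Provides read quality control,
    gapless 1-mismatch matching of reads to transcript sequences, FPKM
    quantification, a pluggable multi-metric differential-expression
    consensus with eight-cluster cross-species classification, parametric
    (PAGE) and singular (SEA) gene-set enrichment, a splice-junction-based
    caller for six alternative-splicing event types, qPCR cross-validation
    via 2^-ddCt, and a synthetic-data generator that plants differentially
    expressed genes and splicing events with a ground-truth table for
    end-to-end recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
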