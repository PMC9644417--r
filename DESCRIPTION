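Package: capig
Title: Targeted Capture Immunoglobulin Sequencing Analysis for Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for hybrid-capture immunoglobulin sequencing of multiple
    myeloma: design of 120-nt capture probes against the 3' ends of V genes
    and 5' ends of J genes from an IMGT-style segment reference; CluMP
    (clustering of mate pairs) translocation calling from discordant
    paired-end reads with soft-clip breakpoint refinement; V(D)J clonotype
    filtering of MiXCR-style clone tables by clonal fraction, cohort
    specificity and absolute clone count; deterministic encoding of
    manual-review breakpoint confirmation rules; sensitivity estimates with
    Wald confidence intervals and dilution-series limit-of-detection
    matrices; and a seeded simulator producing aligned reads with planted
    inter-chromosomal breakpoints and clone-table cohorts with planted
    dominant clones for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tibble,
    stringr,
    stringi,
    purrr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
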