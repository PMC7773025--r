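Package: srnasig
Title: Small RNA Signatures of Exogenous dsRNA Processing in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether topically applied double-stranded RNA (dsRNA) is
    processed into small interfering RNAs (siRNAs) by the plant RNAi machinery
    or merely degraded, from small RNA sequencing read size, strand and position
    signatures against transgenic-target, wild-type and water-sprayed controls.
    Provides a seeded synthetic read generator emulating the experimental
    design, FASTQ adapter trimming and exact strand-aware mapping, size-class
    count tables, a statistical battery (exponential length-decay fits,
    size-class enrichment tests under several normalization schemes,
    sliding-window coverage profiles, transitivity and phasing detection,
    Fisher long/short degradation-ratio test), a DCL-processed versus
    degradation-only classifier, and RNA dose/effective-molarity arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
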