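Package: riboqueue
Title: Codon-Level Ribosome Occupancy, Queuing Detection and Translation
    Efficiency from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of ribosome profiling data:
    A-site assignment of ribosome-protected fragments with a calibratable
    per-read-length offset table, normalized per-codon ribosome occupancy
    (per-gene codon-usage-corrected dwell estimates averaged across genes),
    metagene density profiles around target codons with detection of queued
    -ribosome peaks upstream of stall sites, translation-efficiency ratios
    binned by codon content, and gene-list overlap tests. Includes a
    stochastic footprint simulator with configurable codon dwell times,
    tryptophan-codon stalling and ribosome queuing, so every stage of the
    pipeline can be validated against closed-form expectations.
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
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
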