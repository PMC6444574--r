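Package: tsrnakit
Title: Profiling and Differential Expression of Exosomal tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for tRNA-derived small RNA
    (tsRNA) analysis from raw small RNA-seq reads: adapter trimming and tag
    collapsing, mature/precursor tRNA reference construction with CCA
    addition, hierarchical small-RNA class annotation against per-class
    references, positional tsRNA classification (tRNA-5 / tRNA-i / tRNA-3,
    tRF vs tRH subtypes, precursor 3'U tRFs), composition and length
    profiling, replicate correlation, CPM normalization, two-group
    differential expression with Benjamini-Hochberg FDR control, and
    delta-delta-Ct arithmetic for qPCR validation. Includes a seeded
    synthetic-read generator with full ground truth so every stage can be
    verified without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
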