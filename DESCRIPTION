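Package: atacwell
Title: Single-Nucleus ATAC-Seq Chip Cleanup, Accessibility Matrices and
    Coverage-Based CNV Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microfluidic single-nucleus ATAC-seq experiments:
    a synthetic chip simulator with known ground truth (empty wells,
    doublets, PCR duplicates, cross-well read leakage, hemizygous arm
    deletions), two-stage read cleanup (within-well deduplication and
    cross-well exact-sequence purge) with row/column leakage diagnostics,
    construction and filtering of binary cell-by-peak accessibility
    matrices against a bulk reference peak set, gene-level collapsing,
    marker enrichment and specificity scores, GC-matched sliding-window
    coverage normalization for arm-level copy-number inference, and
    promoter co-accessibility search. Results are tibbles or small S3
    objects with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
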