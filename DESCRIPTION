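Package: clonecall
Title: Clone Calling and Lineage-Coupling Statistics for Barcoded Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clonal lineage analysis of barcoded single-cell RNA-seq
    experiments. Calls clones from combinatorial lentiviral barcodes (fragment
    alignment with mismatch tolerance, directional UMI deduplication, tiered
    dominant-barcode assignment) and from transposon integration barcodes
    (read/UMI filtering, Jaccard similarity with average-linkage clustering).
    Quantifies lineage coupling between cell states with a permutation-null
    z-score statistic and coupling correlations, models barcode collisions as a
    function of labelled-population size and library skew, and maps embryonic
    cells onto postnatal cell-type model vectors by Pearson correlation with
    permutation p-values and FDR gating. Includes seeded generators for
    synthetic barcode read sets and expression matrices with planted clonal and
    marker-gene structure, so the full pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
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
    Biostrings,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
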