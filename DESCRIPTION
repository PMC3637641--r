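Package: rpmeta
Title: Rank Products Differential Expression and Cross-Study Gene-List
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-sample transcriptome comparisons built around the
    Rank Products statistic with a permutation null: per-direction p-values and
    percentage-of-false-prediction estimates, detection-call filtering, strict
    and length-targeted gene-list construction, probeset-to-symbol collapsing,
    cross-study directional concordance and inversion matrices, multi-list
    intersection signatures with Venn-region counts, hypergeometric and
    running-sum (GSEA-style) enrichment statistics, and efficiency-corrected
    (Pfaffl) relative qPCR quantification. Includes a synthetic multi-study
    expression and qPCR plate generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
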