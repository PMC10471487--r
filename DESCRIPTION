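Package: matridrg
Title: Matrisome Expression Profiling of Dorsal Root Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalog-driven profiling of extracellular-matrix ("matrisome")
    gene expression in dorsal root ganglia. Provides matrisome catalog
    bookkeeping with alias resolution and human-mouse ortholog mapping, a
    data-adaptive TPM expression cutoff with per-sample and cohort expression
    calls, per-category expression percentages and cross-species overlap,
    spatial-transcriptomics marker co-expression ratios with an exact Wilcoxon
    matched-pairs signed-rank test, differential-expression overlays, per-cell
    in situ hybridization dot-count quantification, and synthetic-data
    generators that emulate each input so the whole pipeline is testable
    without controlled-access data.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
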