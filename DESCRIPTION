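Package: driftclock
Title: Culture-Time Epigenetic Predictors for Expanded T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying DNA-methylation drift during culture expansion
    of (CAR) T cells: probe and cell-composition filtering of beta matrices,
    reference-based deconvolution of cell fractions, screening for
    cultivation-time-associated CpGs, elastic-net and ridge epigenetic clocks
    for days in culture, per-CpG Cox proportional-hazards screening of
    clinical cohorts, Kaplan-Meier stratification, read-level coherence
    statistics for bisulfite amplicon data, and a synthetic-cohort generator
    with full ground truth for validating every stage.
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
    glmnet,
    jsonlite,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
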