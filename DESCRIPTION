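Package: declineRR
Title: Zero-Replacement Sensitivity Analysis for Log Response Ratio
    Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing how continuity corrections for zero values
    on bounded (percentage or proportion) outcome scales distort log response
    ratio (lnRR) meta-analyses. Computes lnRR effect sizes and delta-method
    sampling variances under configurable zero-replacement policies, screens
    study records with an auditable rule engine, pools effects into
    variance-weighted yearly means (fixed-effect or DerSimonian-Laird
    random-effects), fits Loess trends with bootstrap confidence bands, and
    runs policy-by-screening sensitivity grids that show how a tiny
    replacement constant can manufacture an apparent decline effect. Includes
    a synthetic-corpus generator emulating a decade of ocean-acidification
    fish-behaviour experiments so every claim is testable without external
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
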