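Package: dqscreen
Title: Metadata-Driven Data Quality Assessment for Observational Health Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes data quality indicators for tabular observational
    health-study data, driven by an item-level metadata table. Covers four
    dimensions of data quality: integrity (structural and technical
    compliance), completeness (unit, segment and item missingness, crude and
    qualified), consistency (limit deviations, inadmissible categories,
    two-variable contradiction rules) and accuracy (univariate and
    multivariate outliers, distributional checks, end-digit preference,
    examiner effects via covariate-adjusted marginal means, variance
    components, LOESS time trends). Results are machine-readable indicator
    tables with flagged cell coordinates; reports render to static HTML and
    CSV. A synthetic-study generator with a ground-truth defect ledger makes
    every indicator testable without access to real study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    emmeans,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
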