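Package: faerscreen
Title: Disproportionality Screening of FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection in FDA
    Adverse Event Reporting System (FAERS) quarterly extracts: ingestion of the
    "$"-delimited DEMO/DRUG/REAC ASCII tables and deleted-case lists,
    FDA-recommended deduplication, primary-suspect pediatric cohort selection,
    and four-algorithm disproportionality screening (reporting odds ratio,
    proportional reporting ratio with chi-squared, Bayesian confidence
    propagation neural network information component, and the empirical Bayes
    geometric mean) with configurable signal criteria, gender subgroup
    analysis, and system-organ-class aggregation. Includes a synthetic
    spontaneous-report generator with planted drug-event associations for
    offline validation, and an inversion oracle that recovers contingency
    cells from published statistic sets so printed signal tables can be
    checked without the source database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
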