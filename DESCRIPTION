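Package: rmsperm
Title: Route-Specific Tumor Biomarker Discovery with Restricted Mean
    Survival Permutation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival-analysis pipeline for discovering tumor expression
    biomarkers of benefit from intraperitoneal (IP) versus intravenous (IV)
    adjuvant chemotherapy in ovarian cancer. Implements route-based
    Kaplan-Meier and covariate-adjusted Cox comparisons with 60-month
    administrative truncation, progression-free-survival-stratified
    differential expression with Benjamini-Hochberg adjustment,
    dual-platform (microarray and RNA-Seq) per-standard-deviation Cox
    validation, restricted-mean-survival (RMS) curves over rank-normalized
    expression with bootstrap confidence bands, and permutation tests of
    the IP-minus-IV difference in Cox-adjusted RMS within expression
    quantile windows. Includes a synthetic-cohort generator with
    proportional-hazards survival, two correlated expression platforms and
    configurable missingness, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
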