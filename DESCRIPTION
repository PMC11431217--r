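Package: heatvalid
Title: Validation of ICD-10 Case-Finding Algorithms for Acute Heat Illness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating administrative-data case-finding algorithms
    for acute heat illness (AHI) in emergency department records. Implements
    ICD-10 code-set matching with category-prefix capture, a gold-standard
    chart-review definition (documented heat exposure plus at least one
    heat-related complaint), two-stage diagnostic validation sampling
    (an enriched algorithm-positive sample for positive predictive value and
    a random sample for sensitivity, specificity and negative predictive
    value), proportion confidence intervals by the Wald and continuity-
    corrected Wilson score methods, unweighted Cohen's kappa for inter-rater
    agreement, closed-form diagnostic sample-size planning, and
    temperature-day classification. A synthetic emergency-department cohort
    generator with latent case status, imperfect coding and chart
    documentation, and seasonal daily-maximum-temperature series allows the
    whole pipeline to be exercised and calibrated without access to real
    health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
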