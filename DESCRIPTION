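Package: copdcea
Title: Markov Cohort Cost-Effectiveness Model for Maintenance
    Bronchodilation in COPD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic Markov cohort model of moderate to very severe
    chronic obstructive pulmonary disease (GOLD stages II-IV) with
    within-state exacerbation events, built for cost-utility analysis of
    long-acting bronchodilator therapy in a Swedish setting. Provides the
    packaged base-case inputs (three-month transition matrices and
    exacerbation probabilities derived from the UPLIFT and SPARK trials,
    Swedish direct costs in SEK 2014 and utility weights), a synthetic
    age-differentiated mortality schedule calibrated to published discounted
    life-expectancy anchors, incremental cost-effectiveness analysis
    (ICER/QALY), one-way deterministic sensitivity analysis, and Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
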