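Package: screencea
Title: Decision-Tree Cost-Effectiveness Analysis of Diagnostic Screening Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decision-analytic cost-effectiveness evaluation of
    diagnostic screening strategies: ingredient-based (bottom-up) microcosting
    with capital annualization from a societal perspective, a decision-tree
    model of screening outcomes (true/false positives and negatives driven by
    prevalence, sensitivity and specificity) with expectation rollback,
    incremental cost-effectiveness ratios with absolute and extended dominance
    handling, one-way deterministic sensitivity and threshold (tie-point)
    analyses, and a Monte-Carlo cohort simulator that provides stochastic
    verification of the analytic expected values. Ships a worked example
    comparing point-of-care HbA1c and fasting plasma glucose screening for
    type 2 diabetes in a low-resource outpatient setting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
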