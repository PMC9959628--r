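Package: piradscde
Title: Structured PI-RADS v2.1 Reporting, Scoring, and Reader-Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured prostate mpMRI reporting with PI-RADS v2.1
    common data elements (CDEs): a versioned report schema with validation and
    shape/margin categorization maps, a declarative rule engine mapping CDE
    reports to per-sequence PI-RADS scores and the overall assessment category,
    chance-corrected inter- and intra-rater agreement statistics (percent
    agreement and Gwet's first-order agreement coefficient AC1 with linearized
    variance, confidence intervals, and interpretation bands), reader-study
    analysis tables stratified by session, experience group, and prostate zone,
    diagnostic-accuracy summaries at an ordinal category threshold, and a
    synthetic multi-reader multi-case study generator with a controllable
    confusion-noise model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
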