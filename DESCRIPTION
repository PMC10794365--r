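Package: vrtdx
Title: Viewing Reaction Time Diagnostics for Latency-Based Assessment of
    Sexual Interest in Minors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and inference pipeline for viewing reaction time (VRT)
    data as an indirect measure of pedohebephilic sexual interest in
    help-seeking ("Dunkelfeld") samples. Provides within-person
    ipsatization of response latencies, the max-difference VRT index over
    Tanner-staged stimulus categories, eligibility filtering, three
    missing-latency imputation schemes with Rubin's-rules pooling, a
    dummy-coded interaction regression with SESOI equivalence tests on
    composite nulls, subgroup ROC comparison (bootstrap confidence
    intervals, unpaired DeLong test, Youden cutoff, CI encompassment),
    Spearman criterion-validity correlations, one-way intraclass
    correlations, and a calibrated synthetic-cohort generator for
    validating every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
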