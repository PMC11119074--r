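Package: pharmcat
Title: Pharmacy Complexity Assessment for Sponsored Oncology and
    Haematology Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring engine for the Pharm-CAT pharmacy complexity
    assessment instrument used to grade the pharmacy workload of
    sponsored oncology and haematology clinical trials.  Provides the
    default 15-item instrument as data, validation and total-score
    computation for rater assessments, tertile-based derivation of
    low/medium/high complexity cut-offs, ordinal categorisation,
    inter-rater reproducibility statistics (exact-score concordance,
    score-difference summaries, category cross-classification and
    Cohen's linear weighted kappa), stratified cohort summaries, and a
    seeded synthetic two-rater cohort generator for testing the whole
    pipeline without access to confidential assessment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
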