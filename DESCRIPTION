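Package: mhqtools
Title: Phenotyping and Two-Wave Analysis of Mental Health Questionnaire Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores standard mental-health instruments (PHQ-9, GAD-7, AUDIT,
    CTS-5, UCLA-3 loneliness, Brief Resilience Scale), derives quasi-diagnostic
    lifetime and current psychiatric phenotypes from item-level questionnaire
    responses (CIDI-SF style depression with melancholic and atypical
    specifiers, bipolar type I, panic disorder, eating disorders, self-harm,
    cannabis use, self-reported diagnoses, social isolation), tabulates them
    with epidemiological rounding and small-cell confidentiality rules, and
    analyses two-wave cohorts: age and sex stratified current-disorder
    proportions, relative risks between waves, and test-retest agreement
    (percent agreement, Cohen's kappa, onset-date adjudication). Includes a
    synthetic two-wave cohort generator with latent lifetime disorder status,
    skip logic, reporting noise and item missingness so every stage is
    testable without access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
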