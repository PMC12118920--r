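# mhqtools

Phenotyping and two-wave analysis of mental-health questionnaire cohorts.

Large cohort studies enhance their baseline data with web-based mental
health questionnaires: modules of standard instruments (PHQ-9, GAD-7,
AUDIT, CTS-5, UCLA-3 loneliness, Brief Resilience Scale, EQ-5D VAS) and
structured-interview-style item blocks from which *quasi-diagnostic*
lifetime phenotypes are derived — depression (CIDI-SF style, with
melancholic/atypical specifiers and treatment response), bipolar type I,
panic attack/disorder, four eating disorders, self-harm and suicide
attempt, cannabis use, self-reported clinician diagnoses and social
isolation. When the questionnaire is repeated some years later, the two
waves support longitudinal analyses: age/sex-stratified current-disorder
proportions, between-wave relative risks, and test-retest agreement of
lifetime ("ever") phenotypes.

`mhqtools` is for epidemiologists and psychiatric-genetics researchers who
work with such item-level extracts. It provides:

* **cohort IO** — a data dictionary with value domains, missing-value
  sentinels and skip (routing) rules; a validating loader that
  distinguishes *missing* answers from *skipped* (screened-out) ones;
  wave merging on participant id;
* **instrument scoring** — complete-case totals and caseness, including
  the PHQ-9 diagnostic-algorithm caseness (≥5 items at 2+, item 9 from 1,
  core symptom required);
* **phenotyping** — the lifetime algorithms above under three-valued
  logic (skipped = definite negative; missing propagates only when the
  decision hinges on it), with every threshold in one config block;
* **descriptive tables** — publication percent formatting (whole points,
  one decimal under 10%, half-up), small-cell merging/suppression for
  confidentiality, comorbidity (UPSET-style) overlap counts;
* **longitudinal analysis** — seven-year age bins anchored so 73–79 is a
  bin, stratified proportions, relative risk (risk = proportion
  positive; overall from pooled proportions), 2×2 cross-wave tables,
  percent agreement, Cohen's kappa
  (κ = (p_o − p_e)/(1 − p_e), p_e = p₁p₂ + (1−p₁)(1−p₂)),
  and onset adjudication of wave-2-only positives (onset before the
  wave-1 cutoff vs after/unknown);
* **a synthetic two-wave cohort generator** — latent logistic liabilities
  in age and sex with a shared comorbidity factor, onset years,
  per-phenotype reporting sensitivity/specificity, criteria-exact item
  emission, skip logic, item missingness and module non-completion, plus
  the closed-form `expected_kappa()` to calibrate noise to a target
  test-retest kappa.

## Worked example

Test-retest agreement from a published-style 2×2 cross-wave table
(positive/positive, positive/negative, negative/positive,
negative/negative among both-wave completers):

```r
library(mhqtools)

t <- new_contingency(14612, 11670, 5947, 79046, "lifetime_depression")
t
#> <mhq_contingency> lifetime_depression: ++ 14612, +- 11670, -+ 5947, -- 79046 (N = 111275)
percent_agreement(t)$formatted
#> [1] "84%"
round_half_up(cohens_kappa(t), 2)
#> [1] 0.53
```

84% of participants report the same lifetime-depression status at both
waves, but chance-corrected agreement is only κ = 0.53 — the
multi-criteria symptom definition is much less stable than raw agreement
suggests. Scoring an instrument:

```r
score_phq9(c(3, 3, 2, 2, 2, 0, 0, 0, 1))
#>   total caseness n_missing status
#> 1    13     TRUE         0 scored
```

Total 13 with algorithm caseness: five items at 2+ (item 9 counts at 1)
including a core symptom. And an end-to-end synthetic run:

```r
sim <- generate_cohort(cohort_config(n_participants = 2000, seed = 7))
sim$mhq2
#> <mhq_responses> wave MHQ2: 2000 participants x 122 items (1942 completed all modules)
prof <- derive_phenotypes(sim$mhq2, baseline = sim$baseline)
format_percent(sum(prof$lifetime_depression, na.rm = TRUE),
               sum(!is.na(prof$lifetime_depression)))
#> [1] "17%"
```

The derived lifetime-depression share (17%) sits at the configured 18%
latent prevalence passed through the default reporting-noise model.
`run_pipeline(outdir)` performs the whole chain — simulate, write, reload,
score, phenotype, tabulate, compare waves — and writes every table, the
prevalence figures and a JSON run record.

## Package layout

* `R/dictionary.R`, `R/responses.R` — codebook, loader, validation, skip
  logic, wave merging
* `R/instruments.R` — scale scoring
* `R/phenotyping.R` — lifetime/current phenotype algorithms
* `R/descriptives.R` — formatting, suppression, characteristics table,
  comorbidity overlaps
* `R/longitudinal.R` — bins, stratified proportions, relative risk,
  agreement, kappa, onset adjudication, figures
* `R/synthetic.R` — cohort generator and the closed-form agreement model
* `R/pipeline.R` — end-to-end orchestration with run record
* `vignettes/mhq-phenotyping-methods.Rmd` — models, assumptions, design
  decisions and limitations
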