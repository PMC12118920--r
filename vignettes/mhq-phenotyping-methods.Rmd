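---
title: "Questionnaire phenotyping and two-wave analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Questionnaire phenotyping and two-wave analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhqtools)
```

## What this package computes

`mhqtools` implements the analysis pipeline used for large two-wave
mental-health questionnaire enhancements of volunteer cohorts: item-level
scoring of standard instruments, quasi-diagnostic lifetime phenotype
algorithms, descriptive tables under epidemiological rounding and
disclosure-control rules, and longitudinal comparisons between the two
waves (stratified current-disorder proportions, relative risks, and
test-retest agreement with onset adjudication). The real study data of
this design are access-controlled, so the package ships a synthetic cohort
generator with known ground truth; every downstream stage is exercised and
tested against that truth and against independent brute-force oracles.

"Quasi-diagnostic" is meant literally: the phenotype algorithms are
informed by diagnostic criteria but operate on self-report items alone.
Nothing here is a clinical diagnosis.

## Data model

A wave of data is a wide participant-by-item table (`mhq_responses`):
`pid` plus one integer-coded column per item, governed by a data
dictionary (`mhq_dictionary`) that records each item's module, value
domain, missing-value sentinels and skip (routing) rule. Three answer
states are distinguished:

* a **coded value** in the item's domain;
* **missing** (`NA`) — a blank cell or a sentinel answer such as "prefer
  not to answer" (default codes −818 and −121, dictionary-driven);
* **skipped** (`mhq_skipped()`, internally −9) — the respondent was routed
  past the item by a gate question.

The distinction is load-bearing: a skipped symptom probe is a *definite
negative* (the screener established the criterion cannot be met), whereas
a missing one leaves the criterion undecided and propagates to a missing
phenotype only when the decision actually hinges on it. The algorithms
implement this with three-valued (Kleene) logic plus symptom-count
intervals: a count criterion is definitely met when the observed
endorsements alone reach the threshold, definitely failed when even
endorsing every missing item could not reach it, and undecided otherwise.

Skip rules support several parents with OR semantics (a probe block is
asked when *either* screener is endorsed); the loader classifies blank
cells as skipped exactly when the rule fires, validates value domains, and
computes the completion flag (all applicable items answered) *before*
sentinel normalisation, so "prefer not to answer" counts as an answer.
Participants who did not complete all modules are retained in the table
but excluded from analyses.

## Instrument scoring

PHQ-9, GAD-7, AUDIT, CTS-5, the 3-item UCLA loneliness scale and the
Brief Resilience Scale are scored with a complete-case policy (any missing
item makes the scale missing; no prorating — the source studies do not
document a prorating rule, and complete-case is the conservative choice).
Thresholds that are conventions rather than published constants are
exposed in `instrument_thresholds()`:

* GAD-7 caseness at a total of 10 or more;
* AUDIT harmful drinking at 16 or more;
* PHQ-9 *algorithm* caseness (distinct from the total): at least five
  items at 2+ ("more than half the days"), item 9 counting from 1, with a
  core item (depressed mood or anhedonia) among them;
* CTS-5 domains positive at "sometimes"+ (reverse-keyed "felt loved" at
  "rarely"−), any-domain OR with missing domains dropped;
* BRS low resilience: reverse-keyed mean strictly below 3 (1–2.99 on the
  1–5 scale).

## Lifetime phenotype algorithms

Each algorithm is a conjunction of named criteria with every numeric
threshold collected in `phenotype_thresholds()`:

* **Lifetime depression** (CIDI-SF style): screener (two weeks of low
  mood or anhedonia), at least 5 of 8 symptoms including a core symptom,
  and impairment answered "somewhat" or "a lot" — "a little" rules out.
* **Melancholic / atypical specifiers**: specifier gate (non-reactive or
  reactive mood) plus at least 2 of 4 companion features; definitionally
  false without lifetime depression.
* **Bipolar type I**: elation or irritability gate, at least 3 of 7 manic
  symptoms, episode of a week or more.
* **Panic**: attack = gate plus at least 4 of 13 symptoms; disorder adds
  recurrence, unexpected attacks and a month of concern/behaviour change.
* **Eating disorders**: anorexia (lowest adult BMI ≤ 18.5 from reported
  lowest weight and baseline height, fear-of-gain or gain-preventing
  behaviour, body-image disturbance), bulimia (regular binges and regular
  compensation, not confined to the anorexic low-weight period),
  binge-eating disorder (regular binges, distress, no regular
  compensation), purging disorder (regular purging without binges).
* **Self-harm / suicide attempt**, **cannabis ever / daily**, and the
  **clinician-diagnosis checklist** (any box ticked; "none of the above"
  a definite no) are direct item rules. The first wave's combined "panic
  attacks or panic disorder" checkbox maps onto both split flags of the
  second wave (`sr_panic_harmonisation()`): the combined answer cannot
  distinguish them, so harmonised per-condition panic flags are an upper
  bound by construction.
* **Social isolation**: at least two of lives-alone, visits less than
  monthly, no weekly group activity — with interval logic when an
  indicator is missing.
* **Current depression (composite)** requires caseness on both the PHQ-9
  algorithm and lifetime depression.

Onset years ride along with each dated phenotype; "don't know" is a
distinct code (−1), not missing.

## Descriptive tables

Percentages follow the publication rule: whole points, except one decimal
below 10%. The branch is decided on the unrounded value and rounding is
half-up (the rounding mode is not documented in the source conventions;
half-up at the displayed precision is declared here). Confidentiality:
within a categorical block, rows with any displayed cell of 1–9
participants are pooled into `[Combined]` — minimally, in label order,
extending the pool if the combined row itself remains small. Ethnicity is
special-cased to pool *all* non-White categories plus Missing whenever any
one offends, matching the convention of the tables this reproduces. A cell
that stays small even after pooling (possible in sparse phenotype columns)
is suppressed outright as `<10`; zeros are not disclosive and are never
suppressed. Median (IQR) rows use the inverse-ECDF (type 1) quantile so
integer scores print integer quartiles; this convention is declared, not
inferred from the source.

## Longitudinal analyses

Current-disorder proportions are stratified by wave, sex and seven-year
age bins anchored at 45 (45–51, …, 73–79, 80–86) — the bin width matches
the approximate six-to-seven-year interval between waves, so a participant
typically moves one bin. Age is at completion of the relevant wave, so
individuals can change bins. The relative risk treats the proportion
positive as the risk and divides wave 2 by wave 1 per stratum; the overall
figure uses pooled, unstratified proportions over every both-wave
completer (participants younger than the 45+ analytic range are excluded
from bins but kept in the pooled totals).

Test-retest agreement for the absorbing lifetime phenotypes uses the 2×2
cross-wave table over both-wave completers with non-missing status at both
waves (the exclusion tally is reported). Percent agreement is
(a+d)/N; Cohen's kappa is (p_o − p_e)/(1 − p_e) with
p_e = p₁p₂ + (1−p₁)(1−p₂), reported to two decimals half-up. Of the
wave-2-only positives, onset adjudication counts those whose reported
onset year strictly predates the wave-1 cutoff (default 2016); unknown and
missing onsets group with the *later* onsets, which attributes the largest
possible share of discordance to test-retest variability rather than new
onset. The adjudication column is printed with one decimal regardless of
magnitude, as in the tables it mirrors.

## The synthetic cohort generator

`generate_cohort()` defines the study conditions; its defaults are fixed
once and are not tuning knobs:

* **Cohort structure**: second-wave size `n_participants`; each
  second-wave participant also completed wave 1 with probability 0.65;
  an extra 30% of first-wave-only participants. Ages at wave 2 are uniform
  on 46–86; wave 1 is exactly six years earlier; sex is 58% female.
* **Lifetime liability**: one logistic model per phenotype in age (default
  slopes around −0.3 to −0.6 log-odds per decade, encoding the observed
  decline of lifetime reporting with age), sex (female:male odds ratios,
  up to 8 for eating disorders), and one shared standard-normal factor
  with per-phenotype loadings that induces the comorbidity the overlap
  counts exercise. The intercept is solved numerically so the *marginal*
  prevalence equals the configured value exactly (defaults: depression
  0.18, panic disorder 0.04, anorexia 0.017, purging 0.009, bulimia 0.004,
  binge-eating 0.002, bipolar 0.004, self-harm 0.046, cannabis 0.225, any
  clinician diagnosis 0.33).
* **Onsets** are uniform between age 15 and the age at reporting; by
  default up to wave 2, so a realistic share of onsets falls between the
  waves and exercises adjudication. `onset_latest = "wave1"` restricts
  onsets to before wave 1, the regime in which the closed-form agreement
  model applies. "Don't know" onsets are emitted at rate 0.05.
* **Reporting noise**: per-phenotype, per-wave sensitivity/specificity.
  A latent positive "reports positive" with probability equal to the
  sensitivity, and then receives item answers that satisfy the phenotype
  algorithm *exactly*; a "reports negative" draw violates one necessary
  criterion chosen at random (screener, symptom count, impairment, …).
  There is no published reporting-error model for these instruments, so
  the defaults are calibration knobs chosen once to emulate the
  qualitative retest pattern (multi-criteria symptom definitions less
  stable than yes/no behaviours); analyses that need a *known* kappa use
  `expected_kappa()` / `calibrate_sensitivity()` to solve the noise level
  for a target, as the recovery tests do.
* **Current scales**: wave-1 caseness probabilities follow a logistic
  model in age and sex calibrated to marginal rates (current depression
  0.06, anxiety 0.06, harmful alcohol 0.02) with downward age slopes; the
  wave-2 probability is the configured `wave2_ratio` (defaults 1.07, 0.98,
  0.84) times the participant's *own* wave-1 probability, which makes the
  expected pooled relative risk equal the configured ratio exactly.
* **Missingness**: item-level sentinel answers at rate 0.02 on asked
  non-gate items (gates are spared so the strict "skipped only when the
  rule fires" invariant remains checkable; whole-module non-completion
  still yields missing gates), and 3% module non-completion as a random
  blanked suffix of modules.

What the generator does *not* emulate: the joint covariate distribution of
a real volunteer cohort, recruitment and participation bias, correlated
item-level response styles, or longitudinal drift in reporting thresholds.
Green tests therefore certify the *algorithms and analysis code*, not the
epidemiology of any real population, and the generator makes no claim of
population representativeness.

## Closed-form agreement model

For an absorbing status with pre-wave-1 onset, prevalence p, and
independent misclassification (sens₁, spec₁, sens₂, spec₂), the expected
2×2 cell probabilities are products of the per-wave error rates
(`expected_contingency()`), and `expected_kappa()` is the kappa of that
table. `calibrate_sensitivity()` inverts it for a common per-wave
sensitivity at fixed specificity. The recovery tests generate cohorts at
calibrated noise and check the pipeline-estimated kappa against its target
within three Monte-Carlo standard errors, with the SE estimated by
simulating tables from the expected cell law at the analysis n.

## Numerical choices and degenerate inputs

* Rounding is half-up everywhere a value is displayed (`round_half_up()`),
  never in intermediate computation.
* Kappa is undefined (error) when chance agreement is exactly 1; relative
  risk is undefined (NA, reported as such) when the wave-1 proportion is
  zero; `format_percent()` rejects a zero denominator.
* Empty strata are omitted with their absence visible in the estimates
  table; phenotype columns with zero positives are dropped from the
  characteristics table with a note in `dropped_columns`.
* The eating-disorder triad (bulimia / binge-eating / purging) is made
  mutually consistent both in latents and in noisy reports by the rule's
  own exclusions (compensation excludes binge-eating disorder; binges
  exclude purging disorder).
* Determinism: one seed drives the whole generator; identical
  configuration and seed give byte-identical CSV output.

## Problem sizes

The bundled tests run the generator at 300–20,000 participants for unit
and property checks and at 50,000 for the relative-risk and
kappa-recovery analyses; oracle-equivalence checks use 100,000 random
item vectors per algorithm and the full 5⁵ CTS-5 grid. These sizes give
Monte-Carlo standard errors small enough that three-SE bands are
informative, while a full test run stays comfortably fast on one core.

## Known limitations

* The exact item wording and branching of the bespoke eating-disorder and
  specifier questions in the source instrument are not public; the
  package fixes a faithful DSM-style reconstruction and makes every such
  rule configurable.
* Population-prevalence inference is deliberately out of scope: no
  weights, no confidence intervals on descriptive proportions, following
  the reporting policy of the tables this package reproduces.
* The "helped by treatment" fields cannot distinguish "never exposed"
  from "missing" in the logical columns alone; separate exposure columns
  (`med_exposed`, `ther_exposed`) carry that distinction.
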