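#' Phenotyping thresholds
#'
#' All numeric thresholds used by the quasi-diagnostic lifetime phenotype
#' algorithms, in one configurable block.
#'
#' @param dep_symptoms Minimum endorsed depressive symptoms, screeners
#'   included (default 5).
#' @param dep_impair_min Minimum impairment answer supporting caseness on
#'   the 0 "not at all" to 3 "a lot" scale (default 2 = "somewhat";
#'   "a little" rules out).
#' @param bipolar_symptoms Minimum endorsed manic symptoms (default 3).
#' @param bipolar_duration Minimum episode-duration code (default 2 =
#'   "a week or more").
#' @param panic_symptoms Minimum panic-attack symptoms of the 13 listed
#'   (default 4).
#' @param melancholic_k,atypical_k Companion features required beyond the
#'   specifier gate (default 2 each).
#' @param anorexia_bmi Lowest-adult-BMI threshold (default 18.5).
#' @param isolation_k Isolation indicators required of the three (default 2).
#' @return Named list.
#' @export
phenotype_thresholds <- function(dep_symptoms = 5L, dep_impair_min = 2L,
                                 bipolar_symptoms = 3L, bipolar_duration = 2L,
                                 panic_symptoms = 4L, melancholic_k = 2L,
                                 atypical_k = 2L, anorexia_bmi = 18.5,
                                 isolation_k = 2L) {
  list(dep_symptoms = dep_symptoms, dep_impair_min = dep_impair_min,
       bipolar_symptoms = bipolar_symptoms,
       bipolar_duration = bipolar_duration,
       panic_symptoms = panic_symptoms, melancholic_k = melancholic_k,
       atypical_k = atypical_k, anorexia_bmi = anorexia_bmi,
       isolation_k = isolation_k)
}

# column or all-NA if the wave did not carry the item
.col <- function(d, name) {
  if (name %in% names(d)) d[[name]] else rep(NA_integer_, nrow(d))
}

# item -> endorsement logical; skipped (screened out) is a definite FALSE,
# missing stays NA (three-valued logic then propagates through & and |)
.lv <- function(v) {
  out <- v == 1L
  out[!is.na(v) & v == mhq_skipped()] <- FALSE
  out
}

# item -> integer with skipped as 0
.iv <- function(v) {
  v[!is.na(v) & v == mhq_skipped()] <- 0L
  v
}

# symptom-count interval: observed endorsements and the maximum attainable
# if every missing item were endorsed
.count_range <- function(flags) {
  m <- do.call(cbind, flags)
  list(min = rowSums(m, na.rm = TRUE), max = rowSums(m, na.rm = TRUE) +
         rowSums(is.na(m)))
}

.is_true <- function(x) !is.na(x) & x
.is_false <- function(x) !is.na(x) & !x

# combine definite-true / definite-false evidence into a tri-state logical
.tri <- function(true, false) {
  ifelse(.is_true(true), TRUE, ifelse(.is_true(false), FALSE, NA))
}

# onset kept only where the phenotype is positive; -1 codes "unknown"
.onset_where <- function(onset, status) {
  out <- .iv(onset)
  out[!.is_true(status)] <- NA_integer_
  out
}

#' Lifetime depression (CIDI-SF style)
#'
#' Positive when (a) a screener is endorsed: a two-week or longer period of
#' depressed mood or of anhedonia most of the day; (b) the total endorsed
#' symptom count, screeners plus the six DSM symptom probes, reaches the
#' threshold (default 5) -- a core symptom is guaranteed by the screener;
#' and (c) the worst-episode impairment answer is "somewhat" or "a lot"
#' ("a little" or "not at all" rules out). A screener "no" screens out
#' regardless of other items; missing required items on an undecided path
#' propagate to missing.
#'
#' @param d Wide response tibble (`pid` plus items), e.g.
#'   `response_data(x)`.
#' @param thresholds From [phenotype_thresholds()].
#' @return Tibble with `lifetime_depression` (logical, NA = missing) and
#'   `dep_onset_year` (year; -1 = reported unknown; NA = not applicable).
#' @export
cidisf_depression_lifetime <- function(d, thresholds = phenotype_thresholds()) {
  low <- .lv(.col(d, "dep_screen_low"))
  anh <- .lv(.col(d, "dep_screen_anh"))
  gate <- low | anh
  probes <- lapply(paste0("dep_sym_", c("tired", "appetite", "sleep",
                                        "concentration", "worthless",
                                        "death")),
                   function(nm) .lv(.col(d, nm)))
  cr <- .count_range(c(list(low, anh), probes))
  imp_ok <- .iv(.col(d, "dep_impair")) >= thresholds$dep_impair_min
  true <- gate & (cr$min >= thresholds$dep_symptoms) & imp_ok
  false <- .is_false(gate) | (cr$max < thresholds$dep_symptoms) |
    .is_false(imp_ok)
  status <- .tri(true, false)
  tibble::tibble(
    lifetime_depression = status,
    dep_onset_year = .onset_where(.col(d, "dep_onset_year"), status)
  )
}

#' Melancholic and atypical depression specifiers
#'
#' Within lifetime depression: melancholic requires non-reactive
#' mood/anhedonia plus at least `melancholic_k` of early waking, worse in
#' the morning, marked psychomotor change and excessive guilt; atypical
#' requires mood reactivity plus at least `atypical_k` of weight gain,
#' hypersomnia, leaden heaviness and rejection sensitivity. Both are
#' definitionally `FALSE` without lifetime depression.
#'
#' @inheritParams cidisf_depression_lifetime
#' @param lifetime_depression Logical vector from
#'   [cidisf_depression_lifetime()].
#' @return Tibble with `melancholic`, `atypical`.
#' @export
depression_specifiers <- function(d, lifetime_depression,
                                  thresholds = phenotype_thresholds()) {
  spec_one <- function(gate_item, companions, k) {
    gate <- .lv(.col(d, gate_item))
    cr <- .count_range(lapply(companions, function(nm) .lv(.col(d, nm))))
    true <- lifetime_depression & gate & (cr$min >= k)
    false <- .is_false(lifetime_depression) | .is_false(gate) | (cr$max < k)
    .tri(true, false)
  }
  tibble::tibble(
    melancholic = spec_one(
      "dep_mel_nonreactive",
      c("dep_mel_earlywake", "dep_mel_worsemorning",
        "dep_mel_psychomotor", "dep_mel_guilt"),
      thresholds$melancholic_k
    ),
    atypical = spec_one(
      "dep_aty_reactive",
      c("dep_aty_weightgain", "dep_aty_hypersomnia",
        "dep_aty_leaden", "dep_aty_rejection"),
      thresholds$atypical_k
    )
  )
}

#' Treatment response for depression
#'
#' "Helped" is defined only among the exposed: a participant who never took
#' the treatment has no helped value (NA, with the exposure flag FALSE to
#' distinguish "not applicable" from "missing").
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `med_exposed`, `medication_helped`, `ther_exposed`,
#'   `therapy_helped`.
#' @export
treatment_response <- function(d) {
  one <- function(ever_item, helped_item) {
    exposed <- .lv(.col(d, ever_item))
    helped <- .lv(.col(d, helped_item))
    list(exposed = exposed,
         helped = ifelse(.is_true(exposed), helped, NA))
  }
  med <- one("dep_med_ever", "dep_med_helped")
  ther <- one("dep_ther_ever", "dep_ther_helped")
  tibble::tibble(
    med_exposed = med$exposed, medication_helped = med$helped,
    ther_exposed = ther$exposed, therapy_helped = ther$helped
  )
}

#' Bipolar affective disorder type I
#'
#' Positive when the respondent reports ever a period of extreme elation or
#' extreme irritability, endorses at least `bipolar_symptoms` of the seven
#' manic-symptom items, and the longest episode lasted a week or more.
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `bipolar_i`, `bipolar_onset_year`.
#' @export
bipolar_type_i <- function(d, thresholds = phenotype_thresholds()) {
  gate <- .lv(.col(d, "man_elation")) | .lv(.col(d, "man_irrit"))
  cr <- .count_range(lapply(
    paste0("man_sym_", c("active", "talk", "racing", "sleep", "distract",
                         "confid", "risky")),
    function(nm) .lv(.col(d, nm))
  ))
  dur_ok <- .iv(.col(d, "man_duration")) >= thresholds$bipolar_duration
  true <- gate & (cr$min >= thresholds$bipolar_symptoms) & dur_ok
  false <- .is_false(gate) | (cr$max < thresholds$bipolar_symptoms) |
    .is_false(dur_ok)
  status <- .tri(true, false)
  tibble::tibble(
    bipolar_i = status,
    bipolar_onset_year = .onset_where(.col(d, "man_onset_year"), status)
  )
}

#' Lifetime panic attack and panic disorder (CIDI-SF style)
#'
#' A panic attack ever requires the sudden-episode gate plus at least
#' `panic_symptoms` of the 13 somatic/cognitive symptoms. Panic disorder
#' additionally requires recurrence (more than one attack), some attacks
#' out of the blue, and a month or more of persistent concern or behaviour
#' change.
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `panic_attack_ever`, `panic_disorder`,
#'   `panic_onset_year`.
#' @export
cidisf_panic <- function(d, thresholds = phenotype_thresholds()) {
  gate <- .lv(.col(d, "pan_gate"))
  cr <- .count_range(lapply(paste0("pan_sym_", 1:13),
                            function(nm) .lv(.col(d, nm))))
  attack_true <- gate & (cr$min >= thresholds$panic_symptoms)
  attack_false <- .is_false(gate) | (cr$max < thresholds$panic_symptoms)
  attack <- .tri(attack_true, attack_false)
  rec <- .lv(.col(d, "pan_recurrent"))
  unex <- .lv(.col(d, "pan_unexpected"))
  worry <- .lv(.col(d, "pan_worry_month"))
  disorder <- attack & rec & unex & worry
  tibble::tibble(
    panic_attack_ever = attack,
    panic_disorder = disorder,
    panic_onset_year = .onset_where(.col(d, "pan_onset_year"), disorder)
  )
}

#' Eating-disorder phenotypes
#'
#' Four non-exclusive flags with the stated exclusions. Anorexia: lowest
#' adult BMI at or below the threshold, plus intense fear of weight gain or
#' persistent behaviour preventing gain, plus body-image disturbance at low
#' weight. Bulimia: recurrent binges (large amount with loss of control)
#' and recurrent compensatory behaviour, both at least weekly for three or
#' more months, not exclusively during the anorexic low-weight period.
#' Binge-eating disorder: recurrent weekly binges with marked distress and
#' no regular compensation. Purging disorder: regular compensatory purging
#' without binges. Lowest BMI comes from the reported lowest adult weight
#' and the baseline height.
#'
#' @inheritParams cidisf_depression_lifetime
#' @param height_cm Numeric vector of heights aligned with the rows of `d`
#'   (NA makes anorexia undecidable unless another criterion already fails).
#' @return Tibble with `anorexia`, `bulimia`, `binge_eating`,
#'   `purging_disorder`, `any_eating_disorder`.
#' @export
eating_disorders <- function(d, height_cm = NULL,
                             thresholds = phenotype_thresholds()) {
  if (is.null(height_cm)) height_cm <- rep(NA_real_, nrow(d))
  weight <- .col(d, "ed_lowest_weight_kg")
  bmi <- as.numeric(weight) / (height_cm / 100)^2
  low_bmi <- bmi <= thresholds$anorexia_bmi
  fear <- .lv(.col(d, "ed_fear"))
  prevent <- .lv(.col(d, "ed_prevent"))
  body <- .lv(.col(d, "ed_bodyimage"))
  binge <- .lv(.col(d, "ed_binge"))
  binge_reg <- binge & .lv(.col(d, "ed_binge_weekly_3m"))
  distress <- .lv(.col(d, "ed_distress"))
  ax_only <- .lv(.col(d, "ed_binge_anorexia_only"))
  comp <- .lv(.col(d, "ed_comp"))
  comp_reg <- comp & .lv(.col(d, "ed_comp_weekly_3m"))
  purge <- .lv(.col(d, "ed_comp_purging"))

  anorexia <- low_bmi & (fear | prevent) & body
  bulimia <- binge_reg & comp_reg & !ax_only
  binge_eating <- binge_reg & distress & !comp_reg
  purging <- comp_reg & purge & !binge
  tibble::tibble(
    anorexia = anorexia, bulimia = bulimia, binge_eating = binge_eating,
    purging_disorder = purging,
    any_eating_disorder = anorexia | bulimia | binge_eating | purging
  )
}

#' Self-harm and suicide attempt
#'
#' Self-harm ever is the direct lifetime item; a suicide attempt is
#' self-harm with the intent-to-end-life item endorsed.
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `self_harm_ever`, `suicide_attempt_ever`,
#'   `sh_onset_year`.
#' @export
self_harm_and_suicide <- function(d) {
  sh <- .lv(.col(d, "sh_ever"))
  att <- sh & .lv(.col(d, "sh_intent"))
  tibble::tibble(
    self_harm_ever = sh,
    suicide_attempt_ever = att,
    sh_onset_year = .onset_where(.col(d, "sh_onset_year"), sh)
  )
}

#' Cannabis use
#'
#' Ever-use is any frequency above "never"; daily-use ever is the maximum
#' frequency category.
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `cannabis_ever`, `cannabis_daily_ever`,
#'   `cannabis_onset_year`.
#' @export
cannabis_use <- function(d) {
  freq <- .iv(.col(d, "can_freq"))
  ever <- freq >= 1L
  tibble::tibble(
    cannabis_ever = ever,
    cannabis_daily_ever = freq == 4L,
    cannabis_onset_year = .onset_where(.col(d, "can_onset_year"), ever)
  )
}

#' Mapping of the combined first-wave panic diagnosis checkbox
#'
#' The first wave asked about a clinician diagnosis of "panic attacks or
#' panic disorder" in one checkbox; the second wave asks separately. When
#' harmonising waves the combined answer maps to both second-wave flags.
#'
#' @return A data frame with columns `mhq1_item`, `mhq2_item`.
#' @export
sr_panic_harmonisation <- function() {
  data.frame(
    mhq1_item = "srdx_panic_combined",
    mhq2_item = c("srdx_panic_attacks", "srdx_panic_disorder"),
    stringsAsFactors = FALSE
  )
}

#' Self-reported clinician diagnoses
#'
#' Any diagnosis is at least one condition ticked on the checklist; ticking
#' "none of the above" gives a definite FALSE. First-wave tables carry the
#' combined panic checkbox, which is mapped onto both per-condition panic
#' flags (see [sr_panic_harmonisation()]).
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Tibble with `any_sr_diagnosis` and per-condition flags
#'   `sr_depression`, `sr_bipolar`, `sr_anxiety`, `sr_eating`, `sr_other`,
#'   `sr_panic_attacks`, `sr_panic_disorder`.
#' @export
self_report_diagnosis <- function(d) {
  conds <- list(
    sr_depression = .lv(.col(d, "srdx_depression")),
    sr_bipolar = .lv(.col(d, "srdx_bipolar")),
    sr_anxiety = .lv(.col(d, "srdx_anxiety")),
    sr_eating = .lv(.col(d, "srdx_eating")),
    sr_other = .lv(.col(d, "srdx_other"))
  )
  if ("srdx_panic_combined" %in% names(d)) {
    combined <- .lv(.col(d, "srdx_panic_combined"))
    conds$sr_panic_attacks <- combined
    conds$sr_panic_disorder <- combined
  } else {
    conds$sr_panic_attacks <- .lv(.col(d, "srdx_panic_attacks"))
    conds$sr_panic_disorder <- .lv(.col(d, "srdx_panic_disorder"))
  }
  or_all <- Reduce(`|`, conds)
  none <- .lv(.col(d, "srdx_none"))
  any_sr <- ifelse(.is_true(or_all), TRUE,
                   ifelse(.is_true(none), FALSE, or_all))
  tibble::as_tibble(c(list(any_sr_diagnosis = any_sr), conds))
}

#' Social isolation
#'
#' Three binary indicators: lives alone; visits from friends or family less
#' than monthly; no weekly group activity. Positive when at least
#' `isolation_k` (default 2) are endorsed; if the scored indicators cannot
#' settle the comparison because of a missing one, the result is missing.
#'
#' @inheritParams cidisf_depression_lifetime
#' @return Logical vector.
#' @export
social_isolation <- function(d, thresholds = phenotype_thresholds()) {
  cr <- .count_range(lapply(
    c("soc_lives_alone", "soc_visits_lt_monthly", "soc_no_weekly_activity"),
    function(nm) .lv(.col(d, nm))
  ))
  k <- thresholds$isolation_k
  .tri(cr$min >= k, cr$max < k)
}

#' Current-depression composite case
#'
#' Requires caseness on both the PHQ-9 current-depression algorithm and the
#' lifetime depression algorithm; missing if either input is missing.
#'
#' @param phq9_caseness,lifetime_depression Logical vectors.
#' @return Logical vector.
#' @export
current_depression_case <- function(phq9_caseness, lifetime_depression) {
  phq9_caseness & lifetime_depression
}

#' Any lifetime disorder
#'
#' OR over the four tabulated phenotype groups: lifetime depression, panic
#' disorder, any eating disorder and bipolar type I. "No lifetime criteria"
#' is its complement.
#'
#' @param profile Tibble with the four columns.
#' @return Logical vector.
#' @export
any_lifetime_disorder <- function(profile) {
  profile$lifetime_depression | profile$panic_disorder |
    profile$any_eating_disorder | profile$bipolar_i
}

#' Derive the full phenotype profile for one wave
#'
#' Runs every lifetime/current phenotype algorithm over a response table and
#' returns one row per participant. Scale-based current statuses
#' (PHQ-9/GAD-7/AUDIT caseness) come from [score_instruments()] and are
#' joined in, with the composite current-depression case.
#'
#' @param x An `mhq_responses` object.
#' @param baseline Optional tibble with `pid` and `height_cm` (needed for
#'   the anorexia BMI criterion).
#' @param thresholds From [phenotype_thresholds()].
#' @param instrument_cuts From [instrument_thresholds()].
#' @return Tibble keyed by `pid` with phenotype flags (logical, NA =
#'   missing), onset-year columns (-1 = reported unknown) and current
#'   statuses.
#' @export
derive_phenotypes <- function(x, baseline = NULL,
                              thresholds = phenotype_thresholds(),
                              instrument_cuts = instrument_thresholds()) {
  d <- response_data(x)
  height <- if (!is.null(baseline)) {
    baseline$height_cm[match(d$pid, baseline$pid)]
  } else {
    NULL
  }
  dep <- cidisf_depression_lifetime(d, thresholds)
  spec <- depression_specifiers(d, dep$lifetime_depression, thresholds)
  tr <- treatment_response(d)
  bip <- bipolar_type_i(d, thresholds)
  pan <- cidisf_panic(d, thresholds)
  eat <- eating_disorders(d, height, thresholds)
  sh <- self_harm_and_suicide(d)
  can <- cannabis_use(d)
  sr <- self_report_diagnosis(d)
  scores <- score_instruments(x, instrument_cuts)
  profile <- tibble::tibble(pid = d$pid, completed = x$completed)
  profile <- dplyr::bind_cols(profile, dep, spec, tr, bip, pan, eat, sh, can,
                              sr["any_sr_diagnosis"])
  profile$social_isolation <- social_isolation(d, thresholds)
  profile$adult_adverse_ever <- .lv(.col(d, "adv_adult_ever"))
  profile$any_lifetime_disorder <- any_lifetime_disorder(profile)
  profile$current_depression_phq9 <- scores$phq9_case
  profile$current_depression_case <- current_depression_case(
    scores$phq9_case, profile$lifetime_depression
  )
  profile$current_anxiety_gad7 <- scores$gad7_case
  profile$harmful_alcohol <- scores$audit_harmful
  profile
}
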