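test_that("lifetime depression applies screener, symptom and impairment rules", {
  # screener no rules out regardless of everything else
  d <- dep_row(low = 0L, anh = 0L, probes = rep(mhq_skipped(), 6),
               imp = mhq_skipped())
  expect_false(cidisf_depression_lifetime(d)$lifetime_depression)
  # five symptoms with a core screener and "somewhat" impairment is a case
  d <- dep_row(low = 1L, anh = 0L, probes = c(1L, 1L, 1L, 1L, 0L, 0L),
               imp = 2L, onset = 1999L)
  r <- cidisf_depression_lifetime(d)
  expect_true(r$lifetime_depression)
  expect_identical(r$dep_onset_year, 1999L)
  # identical symptoms but impairment "a little" rules out
  d <- dep_row(low = 1L, anh = 0L, probes = c(1L, 1L, 1L, 1L, 0L, 0L),
               imp = 1L)
  expect_false(cidisf_depression_lifetime(d)$lifetime_depression)
  # four symptoms fall short
  d <- dep_row(low = 1L, anh = 0L, probes = c(1L, 1L, 1L, 0L, 0L, 0L),
               imp = 3L)
  expect_false(cidisf_depression_lifetime(d)$lifetime_depression)
  # undecided path with a missing probe propagates to missing
  d <- dep_row(low = 1L, anh = 0L, probes = c(1L, 1L, 1L, NA, 0L, 0L),
               imp = 3L)
  expect_true(is.na(cidisf_depression_lifetime(d)$lifetime_depression))
  # unknown onset code is carried for positives
  d <- dep_row(low = 1L, anh = 1L, probes = c(1L, 1L, 1L, 0L, 0L, 0L),
               imp = 3L, onset = mhq_onset_unknown())
  expect_identical(cidisf_depression_lifetime(d)$dep_onset_year,
                   mhq_onset_unknown())
})

test_that("specifiers require the parent phenotype and their own gates", {
  base <- dep_row(low = 1L, anh = 0L, probes = c(1L, 1L, 1L, 1L, 0L, 0L),
                  imp = 3L)
  add <- function(d, ...) dplyr::bind_cols(d, tibble::tibble(...))
  # lifetime false forces both specifiers false
  r <- depression_specifiers(base, lifetime_depression = FALSE)
  expect_false(r$melancholic)
  expect_false(r$atypical)
  # reactive mood plus two atypical companions
  d <- add(base, dep_aty_reactive = 1L, dep_aty_weightgain = 1L,
           dep_aty_hypersomnia = 1L, dep_aty_leaden = 0L,
           dep_aty_rejection = 0L, dep_mel_nonreactive = 0L,
           dep_mel_earlywake = 0L, dep_mel_worsemorning = 0L,
           dep_mel_psychomotor = 0L, dep_mel_guilt = 0L)
  r <- depression_specifiers(d, lifetime_depression = TRUE)
  expect_true(r$atypical)
  expect_false(r$melancholic)
  # non-reactive mood alone, no companions: below the count
  d <- add(base, dep_mel_nonreactive = 1L, dep_mel_earlywake = 0L,
           dep_mel_worsemorning = 0L, dep_mel_psychomotor = 0L,
           dep_mel_guilt = 0L, dep_aty_reactive = 0L,
           dep_aty_weightgain = 0L, dep_aty_hypersomnia = 0L,
           dep_aty_leaden = 0L, dep_aty_rejection = 0L)
  expect_false(depression_specifiers(d, TRUE)$melancholic)
})

test_that("treatment response distinguishes unexposed from missing", {
  d <- tibble::tibble(
    pid = c("a", "b", "c"),
    dep_med_ever = c(0L, 1L, 1L),
    dep_med_helped = c(mhq_skipped(), 1L, NA),
    dep_ther_ever = c(1L, 0L, 1L),
    dep_ther_helped = c(0L, mhq_skipped(), 1L)
  )
  r <- treatment_response(d)
  expect_identical(r$med_exposed, c(FALSE, TRUE, TRUE))
  expect_identical(r$medication_helped, c(NA, TRUE, NA))
  expect_identical(r$therapy_helped, c(FALSE, NA, TRUE))
})

test_that("bipolar I needs a gate, three symptoms and a week-long episode", {
  row <- function(el, ir, nsym, dur) {
    syms <- c(rep(1L, nsym), rep(0L, 7 - nsym))
    tibble::tibble(
      pid = "p", man_elation = el, man_irrit = ir,
      man_sym_active = syms[1], man_sym_talk = syms[2],
      man_sym_racing = syms[3], man_sym_sleep = syms[4],
      man_sym_distract = syms[5], man_sym_confid = syms[6],
      man_sym_risky = syms[7], man_duration = dur,
      man_onset_year = 2001L
    )
  }
  expect_false(bipolar_type_i(row(0L, 0L, 0L, 0L))$bipolar_i)
  pos <- bipolar_type_i(row(1L, 0L, 3L, 2L))
  expect_true(pos$bipolar_i)
  expect_identical(pos$bipolar_onset_year, 2001L)
  expect_false(bipolar_type_i(row(1L, 0L, 2L, 2L))$bipolar_i)
  expect_false(bipolar_type_i(row(1L, 0L, 5L, 1L))$bipolar_i)
  expect_true(is.na(bipolar_type_i(row(NA, NA, 5L, 2L))$bipolar_i))
})

test_that("panic attack needs four symptoms; disorder needs the course criteria", {
  row <- function(gate, nsym, rec, unex, worry) {
    d <- tibble::tibble(pid = "p", pan_gate = gate)
    for (j in 1:13) d[[paste0("pan_sym_", j)]] <- as.integer(j <= nsym)
    d$pan_recurrent <- rec
    d$pan_unexpected <- unex
    d$pan_worry_month <- worry
    d$pan_onset_year <- 1995L
    d
  }
  r <- cidisf_panic(row(0L, 0L, mhq_skipped(), mhq_skipped(), mhq_skipped()))
  expect_false(r$panic_attack_ever)
  expect_false(r$panic_disorder)
  r <- cidisf_panic(row(1L, 4L, 1L, 1L, 1L))
  expect_true(r$panic_attack_ever)
  expect_true(r$panic_disorder)
  expect_identical(r$panic_onset_year, 1995L)
  r <- cidisf_panic(row(1L, 3L, 1L, 1L, 1L))
  expect_false(r$panic_attack_ever)
  expect_false(r$panic_disorder)
  # gate endorsed with a fully missing checklist is missing
  d <- row(1L, 0L, 1L, 1L, 1L)
  for (j in 1:13) d[[paste0("pan_sym_", j)]] <- NA_integer_
  expect_true(is.na(cidisf_panic(d)$panic_attack_ever))
})

test_that("eating-disorder flags honour the stated exclusions", {
  row <- function(weight = 70L, fear = 0L, prevent = 0L, body = 0L,
                  binge = 0L, bw = 0L, distress = 0L, axonly = 0L,
                  comp = 0L, cw = 0L, purge = 0L) {
    tibble::tibble(
      pid = "p", ed_lowest_weight_kg = weight, ed_fear = fear,
      ed_prevent = prevent, ed_bodyimage = body, ed_binge = binge,
      ed_binge_weekly_3m = bw, ed_distress = distress,
      ed_binge_anorexia_only = axonly, ed_comp = comp,
      ed_comp_weekly_3m = cw, ed_comp_purging = purge
    )
  }
  h <- 170
  none <- eating_disorders(row(), height_cm = h)
  expect_false(none$any_eating_disorder)
  # BMI 17 with fear and body-image disturbance: anorexia
  w17 <- as.integer(round(17 * (h / 100)^2))
  r <- eating_disorders(row(weight = w17, fear = 1L, body = 1L),
                        height_cm = h)
  expect_true(r$anorexia)
  expect_true(r$any_eating_disorder)
  # weekly binges plus weekly vomiting: bulimia, and the compensation
  # excludes binge-eating disorder
  r <- eating_disorders(row(binge = 1L, bw = 1L, distress = 1L,
                            comp = 1L, cw = 1L, purge = 1L),
                        height_cm = h)
  expect_true(r$bulimia)
  expect_false(r$binge_eating)
  expect_false(r$purging_disorder)  # binges present
  # binges without compensation and with distress: binge-eating disorder
  r <- eating_disorders(row(binge = 1L, bw = 1L, distress = 1L),
                        height_cm = h)
  expect_true(r$binge_eating)
  # purging without binges
  r <- eating_disorders(row(comp = 1L, cw = 1L, purge = 1L), height_cm = h)
  expect_true(r$purging_disorder)
  # missing height makes anorexia missing but not the behavioural flags
  r <- eating_disorders(row(weight = w17, fear = 1L, body = 1L),
                        height_cm = NA_real_)
  expect_true(is.na(r$anorexia))
  expect_false(r$bulimia)
})

test_that("self-harm, suicide attempt, cannabis and diagnosis checklist rules", {
  d <- tibble::tibble(
    pid = c("a", "b", "c"),
    sh_ever = c(0L, 1L, 1L),
    sh_intent = c(mhq_skipped(), 1L, 0L),
    sh_onset_year = c(mhq_skipped(), 1990L, 2005L)
  )
  r <- self_harm_and_suicide(d)
  expect_identical(r$self_harm_ever, c(FALSE, TRUE, TRUE))
  expect_identical(r$suicide_attempt_ever, c(FALSE, TRUE, FALSE))
  expect_identical(r$sh_onset_year, c(NA, 1990L, 2005L))

  d <- tibble::tibble(pid = c("a", "b", "c"),
                      can_freq = c(0L, 4L, 1L),
                      can_onset_year = c(mhq_skipped(), 1980L, 2000L))
  r <- cannabis_use(d)
  expect_identical(r$cannabis_ever, c(FALSE, TRUE, TRUE))
  expect_identical(r$cannabis_daily_ever, c(FALSE, TRUE, FALSE))

  d <- tibble::tibble(
    pid = c("a", "b", "c"),
    srdx_none = c(1L, 0L, 0L),
    srdx_depression = c(0L, 1L, 0L),
    srdx_bipolar = 0L, srdx_anxiety = 0L, srdx_eating = 0L,
    srdx_other = c(0L, 0L, NA),
    srdx_panic_attacks = 0L, srdx_panic_disorder = 0L
  )
  r <- self_report_diagnosis(d)
  expect_identical(r$any_sr_diagnosis, c(FALSE, TRUE, NA))
  # first-wave combined panic checkbox maps onto both split flags
  d1 <- tibble::tibble(pid = "a", srdx_none = 0L, srdx_depression = 0L,
                       srdx_bipolar = 0L, srdx_anxiety = 0L,
                       srdx_eating = 0L, srdx_other = 0L,
                       srdx_panic_combined = 1L)
  r1 <- self_report_diagnosis(d1)
  expect_true(r1$sr_panic_attacks)
  expect_true(r1$sr_panic_disorder)
  expect_true(r1$any_sr_diagnosis)
  expect_identical(nrow(sr_panic_harmonisation()), 2L)
})

test_that("social isolation uses the two-of-three interval rule", {
  d <- tibble::tibble(
    pid = c("a", "b", "c", "d"),
    soc_lives_alone = c(1L, 0L, 1L, 1L),
    soc_visits_lt_monthly = c(1L, 0L, 0L, NA),
    soc_no_weekly_activity = c(0L, 0L, NA, 1L)
  )
  expect_identical(social_isolation(d), c(TRUE, FALSE, NA, TRUE))
})

test_that("current-depression composite is an AND with missing propagation", {
  expect_true(current_depression_case(TRUE, TRUE))
  expect_false(current_depression_case(TRUE, FALSE))
  expect_false(current_depression_case(FALSE, TRUE))
  expect_true(is.na(current_depression_case(NA, TRUE)))
  expect_false(current_depression_case(NA, FALSE))
})

test_that("any-lifetime-disorder is an idempotent OR over the four groups", {
  p <- tibble::tibble(
    lifetime_depression = c(FALSE, TRUE, FALSE, FALSE),
    panic_disorder = c(FALSE, FALSE, TRUE, FALSE),
    any_eating_disorder = c(FALSE, FALSE, TRUE, FALSE),
    bipolar_i = c(FALSE, FALSE, FALSE, NA)
  )
  expect_identical(any_lifetime_disorder(p), c(FALSE, TRUE, TRUE, NA))
})

test_that("algorithms agree with brute-force oracles on random item vectors", {
  set.seed(2024)
  n <- 20000
  # depression over the full tri-state item grid
  d <- tibble::tibble(
    pid = as.character(seq_len(n)),
    dep_screen_low = r_item(n, 0:1), dep_screen_anh = r_item(n, 0:1),
    dep_sym_tired = r_item(n, 0:1), dep_sym_appetite = r_item(n, 0:1),
    dep_sym_sleep = r_item(n, 0:1), dep_sym_concentration = r_item(n, 0:1),
    dep_sym_worthless = r_item(n, 0:1), dep_sym_death = r_item(n, 0:1),
    dep_impair = r_item(n, 0:3), dep_onset_year = r_item(n, 1960:2020)
  )
  got <- cidisf_depression_lifetime(d)$lifetime_depression
  want <- vapply(seq_len(n), function(i) {
    oracle_depression(d$dep_screen_low[i], d$dep_screen_anh[i],
                      c(d$dep_sym_tired[i], d$dep_sym_appetite[i],
                        d$dep_sym_sleep[i], d$dep_sym_concentration[i],
                        d$dep_sym_worthless[i], d$dep_sym_death[i]),
                      d$dep_impair[i])
  }, logical(1))
  expect_identical(got, want)

  # bipolar
  b <- tibble::tibble(pid = as.character(seq_len(n)),
                      man_elation = r_item(n, 0:1),
                      man_irrit = r_item(n, 0:1))
  for (nm in paste0("man_sym_", c("active", "talk", "racing", "sleep",
                                  "distract", "confid", "risky"))) {
    b[[nm]] <- r_item(n, 0:1)
  }
  b$man_duration <- r_item(n, 0:2)
  b$man_onset_year <- r_item(n, 1960:2020)
  got <- bipolar_type_i(b)$bipolar_i
  want <- vapply(seq_len(n), function(i) {
    oracle_bipolar(b$man_elation[i], b$man_irrit[i],
                   as.integer(b[i, paste0("man_sym_",
                                          c("active", "talk", "racing",
                                            "sleep", "distract", "confid",
                                            "risky"))]),
                   b$man_duration[i])
  }, logical(1))
  expect_identical(got, want)

  # panic
  p <- tibble::tibble(pid = as.character(seq_len(n)),
                      pan_gate = r_item(n, 0:1))
  for (j in 1:13) p[[paste0("pan_sym_", j)]] <- r_item(n, 0:1)
  p$pan_recurrent <- r_item(n, 0:1)
  p$pan_unexpected <- r_item(n, 0:1)
  p$pan_worry_month <- r_item(n, 0:1)
  p$pan_onset_year <- r_item(n, 1960:2020)
  got <- cidisf_panic(p)
  want <- lapply(seq_len(n), function(i) {
    oracle_panic(p$pan_gate[i],
                 as.integer(p[i, paste0("pan_sym_", 1:13)]),
                 p$pan_recurrent[i], p$pan_unexpected[i],
                 p$pan_worry_month[i])
  })
  expect_identical(got$panic_attack_ever,
                   vapply(want, `[[`, logical(1), "attack"))
  expect_identical(got$panic_disorder,
                   vapply(want, `[[`, logical(1), "disorder"))

  # social isolation
  s <- tibble::tibble(pid = as.character(seq_len(n)),
                      soc_lives_alone = r_item(n, 0:1),
                      soc_visits_lt_monthly = r_item(n, 0:1),
                      soc_no_weekly_activity = r_item(n, 0:1))
  got <- social_isolation(s)
  want <- vapply(seq_len(n), function(i) {
    oracle_isolation(s$soc_lives_alone[i], s$soc_visits_lt_monthly[i],
                     s$soc_no_weekly_activity[i])
  }, logical(1))
  expect_identical(got, want)
})

test_that("profile hierarchy invariants hold on a noisy generated cohort", {
  sim <- generate_cohort(cohort_config(n_participants = 3000, seed = 17))
  for (x in list(sim$mhq1, sim$mhq2)) {
    prof <- derive_phenotypes(x, baseline = sim$baseline)
    tru <- function(v) !is.na(v) & v
    expect_true(all(tru(prof$suicide_attempt_ever) <=
                      tru(prof$self_harm_ever)))
    expect_true(all(tru(prof$cannabis_daily_ever) <=
                      tru(prof$cannabis_ever)))
    expect_true(all(tru(prof$melancholic) <= tru(prof$lifetime_depression)))
    expect_true(all(tru(prof$atypical) <= tru(prof$lifetime_depression)))
    expect_true(all(tru(prof$panic_disorder) <= tru(prof$panic_attack_ever)))
    expect_identical(
      prof$any_eating_disorder,
      prof$anorexia | prof$bulimia | prof$binge_eating |
        prof$purging_disorder
    )
    expect_identical(
      prof$any_lifetime_disorder,
      prof$lifetime_depression | prof$panic_disorder |
        prof$any_eating_disorder | prof$bipolar_i
    )
    expect_true(all(tru(prof$current_depression_case) <=
                      (tru(prof$current_depression_phq9) &
                         tru(prof$lifetime_depression))))
  }
})

test_that("screen-outs are definite negatives, never missing", {
  # gate a definite no: skipped probes cannot make the result missing
  sim <- generate_cohort(clean_config(1500, 23))
  d <- response_data(sim$mhq2)
  dep <- cidisf_depression_lifetime(d)$lifetime_depression
  screened_out <- d$dep_screen_low == 0L & d$dep_screen_anh == 0L
  expect_true(all(!is.na(dep[screened_out])))
  expect_true(all(!dep[screened_out]))
  pan <- cidisf_panic(d)
  expect_true(all(!pan$panic_attack_ever[d$pan_gate == 0L], na.rm = FALSE))
})

test_that("noise-free synthetic phenotypes equal the ground truth", {
  sim <- generate_cohort(clean_config(2500, 29))
  p2 <- derive_phenotypes(sim$mhq2, baseline = sim$baseline)
  tr <- sim$truth[match(p2$pid, sim$truth$pid), ]
  pairs <- c(
    lifetime_depression = "lifetime_depression_mhq2",
    melancholic = "melancholic_mhq2", atypical = "atypical_mhq2",
    bipolar_i = "bipolar_i_mhq2",
    panic_attack_ever = "panic_attack_ever_mhq2",
    panic_disorder = "panic_disorder_mhq2",
    anorexia = "anorexia_mhq2", bulimia = "bulimia_mhq2",
    binge_eating = "binge_eating_mhq2",
    purging_disorder = "purging_disorder_mhq2",
    any_eating_disorder = "any_eating_disorder_mhq2",
    self_harm_ever = "self_harm_ever_mhq2",
    suicide_attempt_ever = "suicide_attempt_ever_mhq2",
    cannabis_ever = "cannabis_ever_mhq2",
    cannabis_daily_ever = "cannabis_daily_ever_mhq2",
    any_sr_diagnosis = "any_sr_diagnosis_mhq2",
    current_depression_phq9 = "current_depression_mhq2",
    current_anxiety_gad7 = "current_anxiety_mhq2",
    harmful_alcohol = "current_alcohol_mhq2"
  )
  for (nm in names(pairs)) {
    expect_identical(p2[[nm]], unname(tr[[pairs[[nm]]]]), label = nm)
  }
  p1 <- derive_phenotypes(sim$mhq1, baseline = sim$baseline)
  tr1 <- sim$truth[match(p1$pid, sim$truth$pid), ]
  for (nm in c("lifetime_depression", "bipolar_i", "self_harm_ever",
               "cannabis_ever", "any_sr_diagnosis")) {
    expect_identical(p1[[nm]], unname(tr1[[paste0(nm, "_mhq1")]]),
                     label = paste("wave1", nm))
  }
})
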