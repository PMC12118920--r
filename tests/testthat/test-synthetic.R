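test_that("configuration validation rejects infeasible settings", {
  expect_error(cohort_config(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(cohort_config(prevalence = c(depression = 0)), "strictly")
  expect_error(cohort_config(item_missingness_rate = -0.1), "rates")
  expect_error(cohort_config(age_range = c(80, 50)), "increasing")
  expect_error(
    cohort_config(sensitivity = list(MHQ1 = c(depression = 1.4))),
    "sensitivity"
  )
})

test_that("identical config and seed give byte-identical output", {
  cfg <- cohort_config(n_participants = 300, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(a$mhq2, t1)
  write_responses(b$mhq2, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(a$truth, b$truth)
  expect_identical(a$baseline, b$baseline)
  # a different seed changes the draw
  c <- generate_cohort(cfg, seed = 124)
  expect_false(identical(response_data(a$mhq2), response_data(c$mhq2)))
})

test_that("generated tables satisfy the response-table invariants", {
  sim <- generate_cohort(cohort_config(n_participants = 600, seed = 14))
  expect_silent(validate_responses(sim$mhq1))
  expect_silent(validate_responses(sim$mhq2))
})

test_that("noise-free prevalence recovers the configured marginals", {
  prev <- 0.18
  sim <- generate_cohort(clean_config(2000, 7))
  prof <- derive_phenotypes(sim$mhq2, baseline = sim$baseline)
  phat <- mean(prof$lifetime_depression)
  se <- sqrt(prev * (1 - prev) / 2000)
  expect_lt(abs(phat - prev), 3 * se)
  # perfect reporting of an absorbing status: cross-wave agreement is
  # perfect among pre-wave-1 onsets
  both <- intersect(participants(sim$mhq1), participants(sim$mhq2))
  p1 <- derive_phenotypes(sim$mhq1, baseline = sim$baseline)
  p1 <- p1[p1$pid %in% both, ]
  p2 <- prof[prof$pid %in% both, ]
  tr <- sim$truth[match(p1$pid, sim$truth$pid), ]
  pre <- !is.na(tr$dep_onset_year) & tr$dep_onset_year <= 2016
  stable <- pre | is.na(tr$dep_onset_year)  # positives pre-wave-1 or negatives
  t <- build_contingency(p1[stable, ], p2[stable, ], "lifetime_depression")
  expect_identical(t$b, 0L)
  expect_identical(t$c, 0L)
  expect_equal(cohens_kappa(t), 1)
})

test_that("onsets never postdate the wave at which status is positive", {
  sim <- generate_cohort(cohort_config(n_participants = 1500, seed = 77))
  tr <- sim$truth
  for (ph in c("lifetime_depression", "bipolar_i", "self_harm_ever",
               "cannabis_ever")) {
    onset_col <- switch(ph, lifetime_depression = "dep_onset_year",
                        bipolar_i = "bipolar_onset_year",
                        self_harm_ever = "sh_onset_year",
                        cannabis_ever = "cannabis_onset_year")
    pos1 <- tr[[paste0(ph, "_mhq1")]]
    expect_true(all(tr[[onset_col]][pos1] <= 2016))
    # absorbing: positive at wave 1 implies positive at wave 2
    expect_true(all(tr[[paste0(ph, "_mhq2")]][pos1]))
  }
})

test_that("item missingness lands near the configured rate", {
  rate <- 0.02
  sim <- generate_cohort(cohort_config(n_participants = 1200, seed = 41,
                                       completion_rate = 1))
  d <- response_data(sim$mhq2)
  dict <- sim$dictionary
  # eligible cells: asked (non-skipped) non-gate items
  parents <- unique(unlist(lapply(seq_len(nrow(dict)), function(i) {
    r <- mhqtools:::.skip_rule(dict[i, ])
    if (is.null(r)) NULL else names(r)
  })))
  cols <- setdiff(names(d), c("pid", parents))
  m <- as.matrix(d[, cols])
  eligible <- is.na(m) | m != mhq_skipped()
  miss <- sum(is.na(m))
  n_elig <- sum(eligible)
  se <- sqrt(rate * (1 - rate) / n_elig)
  expect_lt(abs(miss / n_elig - rate), 3 * se)
})

test_that("closed-form expected kappa matches simulation and edge cases", {
  expect_equal(expected_kappa(1, 1, 1, 1, 0.3), 1)
  expect_equal(expected_kappa(0.5, 0.5, 0.5, 0.5, 0.42), 0)
  expect_error(expected_kappa(1, 1, 1, 1, 0), "prevalence")
  expect_error(expected_kappa(1, 1, 1, 1, 1), "prevalence")
  # Monte-Carlo cross-check at n = 200,000
  set.seed(61)
  n <- 200000
  prev <- 0.25
  latent <- stats::runif(n) < prev
  obs <- function(sens, spec) {
    ifelse(latent, stats::runif(n) < sens, stats::runif(n) < 1 - spec)
  }
  x1 <- obs(0.75, 0.97)
  x2 <- obs(0.75, 0.97)
  t <- new_contingency(sum(x1 & x2), sum(x1 & !x2), sum(!x1 & x2),
                       sum(!x1 & !x2))
  expect_lt(abs(cohens_kappa(t) - expected_kappa(0.75, 0.97, 0.75, 0.97,
                                                 prev)),
            0.005)
  # cell probabilities sum to one and match the marginals
  cells <- expected_contingency(0.8, 0.95, 0.7, 0.99, 0.1)
  expect_equal(sum(cells), 1)
  expect_equal(unname(cells["a"] + cells["b"]),
               0.1 * 0.8 + 0.9 * 0.05)
})

test_that("calibrated sensitivity attains the target expected kappa", {
  for (target in c(0.3, 0.53, 0.8)) {
    s <- calibrate_sensitivity(target, specificity = 0.98,
                               prevalence = 0.2)
    expect_true(s > 0 && s < 1)
    expect_equal(expected_kappa(s, 0.98, s, 0.98, 0.2), target,
                 tolerance = 1e-8)
  }
})

test_that("pipeline-derived prevalence, agreement and kappa match their
          closed-form expectations under calibrated noise", {
  # moderate-size end-to-end parameter recovery; the acceptance suite
  # repeats this at larger n
  prev <- 0.2
  spec <- 0.98
  sens <- calibrate_sensitivity(0.53, spec, prev)
  sv <- perfect_rates(); sv["depression"] <- sens
  pv <- perfect_rates(); pv["depression"] <- spec
  cfg <- cohort_config(
    n_participants = 12000, seed = 3, overlap_fraction = 1,
    mhq1_only_fraction = 0, prevalence = c(depression = prev),
    sensitivity = list(MHQ1 = sv, MHQ2 = sv),
    specificity = list(MHQ1 = pv, MHQ2 = pv),
    onset_latest = "wave1", item_missingness_rate = 0, completion_rate = 1
  )
  sim <- generate_cohort(cfg)
  p1 <- derive_phenotypes(sim$mhq1, baseline = sim$baseline)
  p2 <- derive_phenotypes(sim$mhq2, baseline = sim$baseline)
  t <- build_contingency(p1, p2, "lifetime_depression")
  cells <- expected_contingency(sens, spec, sens, spec, prev)
  n <- t$n
  # Monte-Carlo SE by simulating tables from the expected cell law
  set.seed(4)
  sims <- stats::rmultinom(400, n, cells)
  ks <- apply(sims, 2, function(x) oracle_kappa(x[1], x[2], x[3], x[4]))
  pas <- (sims[1, ] + sims[4, ]) / n
  expect_lt(abs(cohens_kappa(t) - 0.53), 3 * stats::sd(ks))
  exp_pa <- unname(cells["a"] + cells["d"])
  expect_lt(abs(percent_agreement(t)$proportion - exp_pa),
            3 * stats::sd(pas))
  # observed wave-2 prevalence: latent prevalence through the noise model
  exp_p2 <- prev * sens + (1 - prev) * (1 - spec)
  expect_lt(abs((t$a + t$c) / n - exp_p2),
            3 * sqrt(exp_p2 * (1 - exp_p2) / n))
})
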