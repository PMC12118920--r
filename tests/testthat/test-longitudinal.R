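test_that("seven-year bins anchor so that 73-79 is a bin", {
  expect_identical(seven_year_bins(73L), "73-79")
  expect_identical(seven_year_bins(79L), "73-79")
  expect_identical(seven_year_bins(80L), "80-86")
  expect_identical(seven_year_bins(45L), "45-51")
  expect_identical(seven_year_bins(c(51L, 52L)), c("45-51", "52-58"))
  expect_error(seven_year_bins(44L), "below the 45")
})

test_that("kappa matches a brute-force computation on random tables", {
  set.seed(99)
  for (i in 1:10000) {
    cells <- stats::rmultinom(1, sample(20:5000, 1),
                              prob = stats::runif(4, 0.01, 1))[, 1]
    # avoid degenerate marginals
    if ((cells[1] + cells[2]) %in% c(0, sum(cells))) next
    if ((cells[1] + cells[3]) %in% c(0, sum(cells))) next
    t <- new_contingency(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(cohens_kappa(t) -
                    oracle_kappa(cells[1], cells[2], cells[3], cells[4])),
              1e-12)
  }
})

test_that("kappa symmetry, bounds and agreement identity", {
  set.seed(7)
  for (i in 1:200) {
    cells <- stats::rmultinom(1, 2000, prob = stats::runif(4, 0.05, 1))[, 1]
    t <- new_contingency(cells[1], cells[2], cells[3], cells[4])
    sw <- new_contingency(cells[1], cells[3], cells[2], cells[4])
    # swapping waves swaps b and c and leaves kappa unchanged
    expect_equal(cohens_kappa(t), cohens_kappa(sw), tolerance = 1e-12)
    k <- cohens_kappa(t)
    expect_true(k >= -1 && k <= 1)
    # percent agreement equals the kappa-implied bound p_e + k(1 - p_e)
    p1 <- (t$a + t$b) / t$n
    p2 <- (t$a + t$c) / t$n
    pe <- p1 * p2 + (1 - p1) * (1 - p2)
    expect_gte(percent_agreement(t)$proportion + 1e-12, pe + k * (1 - pe))
  }
  # perfect agreement iff both off-diagonal cells empty
  expect_equal(cohens_kappa(new_contingency(50, 0, 0, 150)), 1)
  expect_lt(cohens_kappa(new_contingency(50, 1, 0, 149)), 1)
  expect_error(cohens_kappa(new_contingency(10, 0, 0, 0)), "degenerate")
})

test_that("agreement and adjudication reproduce the published retest rows", {
  rows <- list(
    depression = list(cells = c(14612, 11670, 5947, 79046),
                      agree = "84%", kappa = 0.53, adj = c(4445L, 5947L),
                      adj_fmt = "74.7%"),
    bipolar = list(cells = c(157, 448, 279, 110391),
                   agree = "99%", kappa = 0.30, adj = c(250L, 279L),
                   adj_fmt = "89.6%"),
    self_harm = list(cells = c(3498, 1411, 1788, 104578),
                     agree = "97%", kappa = 0.67, adj = c(1378L, 1788L),
                     adj_fmt = "77.1%"),
    cannabis = list(cells = c(21630, 4015, 3393, 82237),
                    agree = "93%", kappa = 0.81, adj = c(3139L, 3393L),
                    adj_fmt = "92.5%"),
    sr_diagnosis = list(cells = c(25701, 11678, 4286, 69610),
                        agree = "86%", kappa = 0.66)
  )
  for (nm in names(rows)) {
    r <- rows[[nm]]
    t <- new_contingency(r$cells[1], r$cells[2], r$cells[3], r$cells[4], nm)
    expect_identical(t$n, 111275)
    expect_identical(percent_agreement(t)$formatted, r$agree)
    expect_equal(round_half_up(cohens_kappa(t), 2), r$kappa)
    if (!is.null(r$adj)) {
      onsets <- c(rep(2000L, r$adj[1]), rep(2020L, r$adj[2] - r$adj[1]))
      adj <- onset_adjudication(onsets, cutoff_year = 2016L)
      expect_identical(adj$n_early, r$adj[1])
      expect_identical(adj$formatted, r$adj_fmt)
    }
  }
})

test_that("unknown and missing onsets group with the later onsets", {
  adj <- onset_adjudication(rep(mhq_onset_unknown(), 20))
  expect_identical(adj$n_early, 0L)
  expect_identical(adj$formatted, "0.0%")
  mix <- onset_adjudication(c(2010L, 2015L, 2016L, 2017L,
                              mhq_onset_unknown(), NA))
  expect_identical(mix$n_early, 2L)  # strictly before the cutoff
  expect_identical(mix$n_total, 6L)
})

test_that("contingency construction matches per-participant cross-tabulation", {
  set.seed(21)
  n <- 5000
  p1 <- tibble::tibble(pid = as.character(seq_len(n)),
                       st = sample(c(TRUE, FALSE, NA), n, TRUE,
                                   prob = c(.2, .75, .05)))
  p2 <- tibble::tibble(pid = sample(p1$pid),  # shuffled join order
                       st = sample(c(TRUE, FALSE, NA), n, TRUE,
                                   prob = c(.25, .7, .05)))
  t <- build_contingency(p1, p2, "st", onset_column = NA_character_)
  m <- match(p1$pid, p2$pid)
  s1 <- p1$st
  s2 <- p2$st[m]
  ok <- !is.na(s1) & !is.na(s2)
  expect_identical(t$a, sum(s1 & s2, na.rm = TRUE) -
                     sum(s1 & s2 & !ok, na.rm = TRUE))
  expect_identical(t$a, sum(ok & s1 & s2))
  expect_identical(t$b, sum(ok & s1 & !s2))
  expect_identical(t$c, sum(ok & !s1 & s2))
  expect_identical(t$d, sum(ok & !s1 & !s2))
  expect_identical(t$n_excluded, sum(!ok))
  expect_identical(t$n, sum(ok))
  # everyone negative at both waves
  q1 <- tibble::tibble(pid = c("a", "b"), st = FALSE)
  t0 <- build_contingency(q1, q1, "st", onset_column = NA_character_)
  expect_identical(c(t0$a, t0$b, t0$c, t0$d), c(0L, 0L, 0L, 2L))
  expect_identical(percent_agreement(t0)$formatted, "100%")
})

test_that("independent coin-flip statuses give kappa near zero", {
  set.seed(33)
  n <- 10000
  p1 <- tibble::tibble(pid = as.character(seq_len(n)),
                       st = sample(c(TRUE, FALSE), n, TRUE))
  p2 <- tibble::tibble(pid = p1$pid,
                       st = sample(c(TRUE, FALSE), n, TRUE))
  t <- build_contingency(p1, p2, "st", onset_column = NA_character_)
  se <- 1 / sqrt(n)  # asymptotic SE of kappa under independence, p = 1/2
  expect_lt(abs(cohens_kappa(t)), 3 * se)
})

test_that("stratified proportions match a brute-force group-by oracle", {
  set.seed(55)
  n <- 4000
  data <- tibble::tibble(
    pid = rep(as.character(seq_len(n / 2)), 2),
    wave = rep(c("MHQ1", "MHQ2"), each = n / 2),
    sex = sample(c("female", "male"), n, TRUE),
    age = sample(45:86, n, TRUE),
    current_depression = sample(c(TRUE, FALSE, NA), n, TRUE,
                                prob = c(.1, .85, .05)),
    current_anxiety = sample(c(TRUE, FALSE), n, TRUE, prob = c(.08, .92)),
    harmful_alcohol = sample(c(TRUE, FALSE), n, TRUE, prob = c(.03, .97))
  )
  est <- stratified_proportions(data)
  for (i in sample(nrow(est), 50)) {
    row <- est[i, ]
    sel <- data$wave == row$wave & data$sex == row$sex &
      seven_year_bins(data$age) == row$age_bin &
      !is.na(data[[row$phenotype]])
    expect_identical(row$n, sum(sel))
    expect_identical(row$n_positive, sum(data[[row$phenotype]][sel]))
    expect_equal(row$proportion, mean(data[[row$phenotype]][sel]))
  }
  # empty strata are omitted
  expect_true(all(est$n > 0))
})

test_that("relative risk divides second-wave by first-wave proportions", {
  strata <- tibble::tibble(
    wave = c("MHQ1", "MHQ2", "MHQ1", "MHQ2"),
    sex = "female",
    age_bin = c("73-79", "73-79", "80-86", "80-86"),
    phenotype = "current_depression",
    n = c(100L, 120L, 50L, 60L),
    n_positive = c(8L, 12L, 0L, 3L)
  )
  strata$proportion <- strata$n_positive / strata$n
  rr <- relative_risk(strata)
  r1 <- rr[rr$age_bin == "73-79", ]
  expect_equal(r1$rr, (12 / 120) / (8 / 100))
  # identical proportions give rr = 1
  expect_equal(relative_risk(tibble::tibble(
    wave = c("MHQ1", "MHQ2"), sex = "m", age_bin = "45-51",
    phenotype = "x", n = c(100L, 200L), n_positive = c(8L, 16L),
    proportion = c(0.08, 0.08)
  ))$rr, c(1, 1))
  # zero first-wave risk is undefined
  r0 <- rr[rr$age_bin == "80-86", ]
  expect_true(is.na(r0$rr))
})
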