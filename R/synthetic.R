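#' Configuration for the synthetic two-wave cohort generator
#'
#' The generator draws a cohort with latent lifetime disorder status (a
#' logistic liability in age and sex per phenotype, plus one shared
#' standard-normal comorbidity factor), onset years, wave-specific
#' reporting noise (per-phenotype sensitivity/specificity), current-symptom
#' severities with an age gradient and a configurable between-wave risk
#' ratio, full skip logic, item missingness and module non-completion.
#' Identical configuration and seed give byte-identical output.
#'
#' @param n_participants Second-wave cohort size.
#' @param overlap_fraction Probability a second-wave participant also
#'   completed the first wave.
#' @param mhq1_only_fraction Extra first-wave-only participants, as a
#'   fraction of `n_participants`.
#' @param age_range Integer age bounds at the second wave (default 46-86;
#'   the first wave is six years earlier).
#' @param sex_split Probability of female sex.
#' @param wave_years Named years of the two waves.
#' @param prevalence Named marginal lifetime prevalences at the second wave
#'   (see `default_prevalence()` in the source for the keys).
#' @param age_slope Named log-odds slopes per decade of age.
#' @param sex_or Named female:male odds ratios.
#' @param comorbidity_loading Named loadings on the shared liability factor.
#' @param sensitivity,specificity Lists with elements `MHQ1` and `MHQ2`,
#'   each a named per-phenotype vector: the probability that a
#'   true-positive (true-negative) latent status yields criteria-meeting
#'   (criteria-failing) item responses at that wave.
#' @param onset_age_min Earliest onset age.
#' @param onset_latest `"wave2"` (onsets up to the age at the second wave;
#'   some onsets then fall between waves) or `"wave1"` (all onsets predate
#'   the first wave, matching the closed-form agreement model).
#' @param onset_unknown_rate Probability an onset is reported "don't know".
#' @param current Per-scale current-disorder model: lists with `base`
#'   (marginal first-wave rate), `age_slope` (log-odds per decade),
#'   `sex_or`, and `wave2_ratio` (the imposed second-to-first-wave risk
#'   ratio applied to each participant's own first-wave probability).
#' @param item_missingness_rate Probability an asked non-gate item is
#'   answered with a missing-value sentinel.
#' @param completion_rate Probability a participant completes all modules.
#' @param seed Integer RNG seed.
#' @return A validated `mhq_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 20000L,
                          overlap_fraction = 0.65,
                          mhq1_only_fraction = 0.3,
                          age_range = c(46L, 86L),
                          sex_split = 0.58,
                          wave_years = c(MHQ1 = 2016L, MHQ2 = 2022L),
                          prevalence = NULL,
                          age_slope = NULL,
                          sex_or = NULL,
                          comorbidity_loading = NULL,
                          sensitivity = NULL,
                          specificity = NULL,
                          onset_age_min = 15L,
                          onset_latest = c("wave2", "wave1"),
                          onset_unknown_rate = 0.05,
                          current = NULL,
                          item_missingness_rate = 0.02,
                          completion_rate = 0.97,
                          seed = 1L) {
  onset_latest <- match.arg(onset_latest)
  cfg <- list(
    n_participants = as.integer(n_participants),
    overlap_fraction = overlap_fraction,
    mhq1_only_fraction = mhq1_only_fraction,
    age_range = as.integer(age_range),
    sex_split = sex_split,
    wave_years = wave_years,
    prevalence = .merge_named(.default_prevalence(), prevalence),
    age_slope = .merge_named(.default_age_slope(), age_slope),
    sex_or = .merge_named(.default_sex_or(), sex_or),
    comorbidity_loading = .merge_named(.default_loading(),
                                       comorbidity_loading),
    sensitivity = list(
      MHQ1 = .merge_named(.default_sensitivity(),
                          sensitivity$MHQ1 %||% sensitivity),
      MHQ2 = .merge_named(.default_sensitivity(),
                          sensitivity$MHQ2 %||% sensitivity)
    ),
    specificity = list(
      MHQ1 = .merge_named(.default_specificity(),
                          specificity$MHQ1 %||% specificity),
      MHQ2 = .merge_named(.default_specificity(),
                          specificity$MHQ2 %||% specificity)
    ),
    onset_age_min = as.integer(onset_age_min),
    onset_latest = onset_latest,
    onset_unknown_rate = onset_unknown_rate,
    current = .merge_current(.default_current(), current),
    item_missingness_rate = item_missingness_rate,
    completion_rate = completion_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "mhq_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.merge_named <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  override <- unlist(override)
  defaults[names(override)] <- override
  defaults
}

.merge_current <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) {
    defaults[[nm]][names(override[[nm]])] <- override[[nm]]
  }
  defaults
}

# marginal lifetime prevalences at the second wave; values emulate a large
# volunteer cohort aged 46-86
.default_prevalence <- function() {
  c(depression = 0.18, bipolar = 0.004, panic_disorder = 0.04,
    panic_attack_extra = 0.04, anorexia = 0.017, bulimia = 0.004,
    binge_eating = 0.002, purging = 0.009, self_harm = 0.046,
    cannabis = 0.225, sr_diagnosis = 0.33)
}

.default_age_slope <- function() {
  c(depression = -0.45, bipolar = -0.4, panic_disorder = -0.5,
    panic_attack_extra = -0.5, anorexia = -0.6, bulimia = -0.6,
    binge_eating = -0.6, purging = -0.6, self_harm = -0.5,
    cannabis = -0.6, sr_diagnosis = -0.3)
}

.default_sex_or <- function() {
  c(depression = 2.0, bipolar = 1.6, panic_disorder = 2.1,
    panic_attack_extra = 2.0, anorexia = 8, bulimia = 8, binge_eating = 8,
    purging = 8, self_harm = 1.8, cannabis = 0.7, sr_diagnosis = 2.0)
}

.default_loading <- function() {
  c(depression = 0.8, bipolar = 0.8, panic_disorder = 0.8,
    panic_attack_extra = 0.7, anorexia = 0.6, bulimia = 0.6,
    binge_eating = 0.6, purging = 0.6, self_harm = 0.8, cannabis = 0.2,
    sr_diagnosis = 0.9)
}

# reporting-noise defaults emulate the qualitative retest pattern:
# multi-criteria symptom definitions are less stable than yes/no behaviours
.default_sensitivity <- function() {
  c(depression = 0.78, bipolar = 0.4, panic_disorder = 0.8, anorexia = 0.8,
    bulimia = 0.8, binge_eating = 0.8, purging = 0.8, self_harm = 0.75,
    cannabis = 0.9, sr_diagnosis = 0.82)
}

.default_specificity <- function() {
  c(depression = 0.965, bipolar = 0.997, panic_disorder = 0.995,
    anorexia = 0.998, bulimia = 0.999, binge_eating = 0.999,
    purging = 0.998, self_harm = 0.995, cannabis = 0.99,
    sr_diagnosis = 0.97)
}

.default_current <- function() {
  list(
    depression = c(base = 0.06, age_slope = -0.35, sex_or = 1.4,
                   wave2_ratio = 1.07),
    anxiety = c(base = 0.06, age_slope = -0.4, sex_or = 1.6,
                wave2_ratio = 0.98),
    alcohol = c(base = 0.02, age_slope = -0.5, sex_or = 0.4,
                wave2_ratio = 0.84)
  )
}

#' Validate a cohort configuration
#' @param cfg A `mhq_cohort_config`.
#' @return `cfg` invisibly, or an error.
#' @export
validate_cohort_config <- function(cfg) {
  in01 <- function(x) all(x >= 0 & x <= 1)
  if (cfg$n_participants < 1) stop("n_participants must be positive",
                                   call. = FALSE)
  if (!in01(cfg$overlap_fraction)) {
    stop("overlap_fraction must lie in [0,1]", call. = FALSE)
  }
  if (any(cfg$prevalence <= 0 | cfg$prevalence >= 1)) {
    stop("prevalences must lie strictly between 0 and 1", call. = FALSE)
  }
  for (w in c("MHQ1", "MHQ2")) {
    if (!in01(cfg$sensitivity[[w]]) || !in01(cfg$specificity[[w]])) {
      stop("sensitivity/specificity must lie in [0,1]", call. = FALSE)
    }
  }
  if (!in01(c(cfg$item_missingness_rate, cfg$completion_rate,
              cfg$onset_unknown_rate, cfg$sex_split))) {
    stop("rates must lie in [0,1]", call. = FALSE)
  }
  if (cfg$age_range[1] > cfg$age_range[2]) {
    stop("age_range must be increasing", call. = FALSE)
  }
  invisible(cfg)
}

#' Expected cross-wave 2x2 cell probabilities under independent
#' misclassification
#'
#' For a stable (absorbing, pre-wave-1 onset) latent status with prevalence
#' `prevalence`, observed at two waves with the given per-wave sensitivity
#' and specificity and independent errors, returns the implied cell
#' probabilities (both positive; first only; second only; neither).
#'
#' @param sens1,spec1,sens2,spec2 Per-wave misclassification parameters.
#' @param prevalence Latent prevalence, strictly inside (0,1).
#' @return Named numeric vector `c(a, b, c, d)` summing to 1.
#' @export
expected_contingency <- function(sens1, spec1, sens2, spec2, prevalence) {
  if (any(c(sens1, spec1, sens2, spec2) < 0 |
            c(sens1, spec1, sens2, spec2) > 1)) {
    stop("sensitivity/specificity must lie in [0,1]", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- prevalence
  a <- p * sens1 * sens2 + (1 - p) * (1 - spec1) * (1 - spec2)
  b <- p * sens1 * (1 - sens2) + (1 - p) * (1 - spec1) * spec2
  cc <- p * (1 - sens1) * sens2 + (1 - p) * spec1 * (1 - spec2)
  d <- p * (1 - sens1) * (1 - sens2) + (1 - p) * spec1 * spec2
  c(a = a, b = b, c = cc, d = d)
}

#' Closed-form expected Cohen's kappa under independent misclassification
#'
#' The kappa of the 2x2 table implied by observing one stable latent status
#' at two waves with independent errors. Used to calibrate the generator's
#' reporting noise toward a target test-retest kappa.
#'
#' @inheritParams expected_contingency
#' @return Expected kappa.
#' @export
expected_kappa <- function(sens1, spec1, sens2, spec2, prevalence) {
  cells <- expected_contingency(sens1, spec1, sens2, spec2, prevalence)
  p_o <- cells["a"] + cells["d"]
  p1 <- cells["a"] + cells["b"]
  p2 <- cells["a"] + cells["c"]
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  unname((p_o - p_e) / (1 - p_e))
}

#' Solve the sensitivity that attains a target expected kappa
#'
#' Holds specificity fixed at both waves and finds the common per-wave
#' sensitivity whose [expected_kappa()] equals the target.
#'
#' @param target Target kappa.
#' @param specificity Fixed per-wave specificity.
#' @param prevalence Latent prevalence.
#' @return Sensitivity in (0,1).
#' @export
calibrate_sensitivity <- function(target, specificity, prevalence) {
  f <- function(s) expected_kappa(s, specificity, s, specificity,
                                  prevalence) - target
  stats::uniroot(f, c(1e-3, 1 - 1e-9), tol = 1e-10)$root
}

.rbern <- function(n, p) stats::runif(n) < p

# exactly k[i] TRUE per row over ncol columns (uniformly placed)
.pick_k <- function(n, k, ncol) {
  if (n == 0) return(matrix(logical(0), 0, ncol))
  r <- matrix(stats::runif(n * ncol), n, ncol)
  srt <- apply(r, 1, sort)
  if (is.null(dim(srt))) srt <- matrix(srt, nrow = ncol)
  kth <- srt[cbind(pmax(k, 1L), seq_len(n))]
  th <- ifelse(k == 0L, -Inf, kth)
  r <= matrix(th, n, ncol)
}

# intercept such that mean(plogis(a + lp)) hits the target marginal
.solve_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 c(-30, 30), tol = 1e-10)$root
}

.draw_latent <- function(prev, slope, lor_sex, loading, age2, female, u) {
  lp <- slope * (age2 - 65) / 10 + lor_sex * female + loading * u
  a <- .solve_intercept(lp, prev)
  .rbern(length(age2), stats::plogis(a + lp))
}

#' Generate a synthetic two-wave cohort
#'
#' Draws baseline covariates, latent lifetime phenotypes with onset years,
#' per-wave reporting decisions and criteria-exact item responses (a
#' participant sampled as "reports positive" receives answers that satisfy
#' the corresponding phenotype algorithm; "reports negative" violates a
#' necessary criterion chosen at random), then applies skip logic, item
#' missingness and module non-completion.
#'
#' @param config From [cohort_config()].
#' @param seed Overrides `config$seed`.
#' @return List with `mhq1` and `mhq2` (`mhq_responses`), `baseline`
#'   (tibble), `truth` (tibble of latent statuses, per-wave true statuses,
#'   report decisions, onsets and current statuses), `dictionary`, and
#'   `counts` (wave-partition bookkeeping).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  cfg <- config
  dict <- mhq_dictionary()

  n2 <- cfg$n_participants
  n1o <- as.integer(round(n2 * cfg$mhq1_only_fraction))
  N <- n2 + n1o
  pid <- sprintf("P%06d", seq_len(N))
  in_mhq2 <- c(rep(TRUE, n2), rep(FALSE, n1o))
  in_mhq1 <- c(.rbern(n2, cfg$overlap_fraction), rep(TRUE, n1o))

  age2 <- sample(seq.int(cfg$age_range[1], cfg$age_range[2]), N,
                 replace = TRUE)
  age1 <- as.integer(age2 - (cfg$wave_years[["MHQ2"]] -
                               cfg$wave_years[["MHQ1"]]))
  female <- .rbern(N, cfg$sex_split)
  height_cm <- round(stats::rnorm(N, 168, 9))
  birth_month <- sample.int(12, N, replace = TRUE)
  birth_year <- as.integer(cfg$wave_years["MHQ2"]) - age2 -
    as.integer(birth_month > 11L)
  u <- stats::rnorm(N)

  # lifetime latents with calibrated marginals
  lat <- lapply(names(cfg$prevalence), function(ph) {
    .draw_latent(cfg$prevalence[[ph]], cfg$age_slope[[ph]],
                 log(cfg$sex_or[[ph]]), cfg$comorbidity_loading[[ph]],
                 age2, female, u)
  })
  names(lat) <- names(cfg$prevalence)
  # the binge/compensation triad flags are mutually exclusive by rule
  lat$binge_eating <- lat$binge_eating & !lat$bulimia
  lat$purging <- lat$purging & !lat$bulimia & !lat$binge_eating
  lat$panic_attack <- lat$panic_disorder | lat$panic_attack_extra

  # conditional latents
  lat$suicide_intent <- lat$self_harm & .rbern(N, 0.35)
  lat$cannabis_daily <- lat$cannabis & .rbern(N, 0.15)
  lat$melancholic <- lat$depression & .rbern(N, 0.3)
  lat$atypical <- lat$depression & !lat$melancholic & .rbern(N, 0.25)
  lat$med_exposed <- .rbern(N, 0.55)
  lat$med_helped <- .rbern(N, 0.65)
  lat$ther_exposed <- .rbern(N, 0.5)
  lat$ther_helped <- .rbern(N, 0.6)
  # self-report diagnosis ticks, stable across waves
  lat$sr_tick_dep <- lat$sr_diagnosis & lat$depression & .rbern(N, 0.75)
  lat$sr_tick_bip <- lat$sr_diagnosis & lat$bipolar & .rbern(N, 0.7)
  lat$sr_tick_anx <- lat$sr_diagnosis & .rbern(N, 0.4)
  lat$sr_tick_eat <- lat$sr_diagnosis &
    (lat$anorexia | lat$bulimia | lat$binge_eating | lat$purging) &
    .rbern(N, 0.5)
  lat$sr_tick_pan <- lat$sr_diagnosis & lat$panic_attack & .rbern(N, 0.5)
  lat$sr_tick_oth <- lat$sr_diagnosis & .rbern(N, 0.3)

  # onset years for the dated phenotypes
  onset_cap_age <- if (cfg$onset_latest == "wave1") age1 else age2
  draw_onset <- function(latent) {
    span <- pmax(onset_cap_age - cfg$onset_age_min, 0L)
    oa <- cfg$onset_age_min + floor(stats::runif(N) * (span + 1))
    oy <- as.integer(cfg$wave_years["MHQ2"]) - (age2 - as.integer(oa))
    oy[!latent] <- NA_integer_
    oy
  }
  onsets <- list(
    depression = draw_onset(lat$depression),
    bipolar = draw_onset(lat$bipolar),
    panic_disorder = draw_onset(lat$panic_disorder | lat$panic_attack),
    self_harm = draw_onset(lat$self_harm),
    cannabis = draw_onset(lat$cannabis)
  )

  # true status at each wave: latent with onset no later than the wave
  status_at <- function(ph, wave) {
    yr <- as.integer(cfg$wave_years[[wave]])
    if (ph %in% names(onsets)) {
      lat[[ph]] & !is.na(onsets[[ph]]) & onsets[[ph]] <= yr
    } else {
      lat[[ph]]
    }
  }
  noisy <- function(st, sens, spec) {
    ifelse(st, .rbern(N, sens), .rbern(N, 1 - spec))
  }
  report <- list()
  for (w in c("MHQ1", "MHQ2")) {
    sv <- cfg$sensitivity[[w]]
    pv <- cfg$specificity[[w]]
    report[[w]] <- list(
      depression = noisy(status_at("depression", w),
                         sv["depression"], pv["depression"]),
      bipolar = noisy(status_at("bipolar", w), sv["bipolar"], pv["bipolar"]),
      panic_disorder = noisy(status_at("panic_disorder", w),
                             sv["panic_disorder"], pv["panic_disorder"]),
      anorexia = noisy(status_at("anorexia", w), sv["anorexia"],
                       pv["anorexia"]),
      bulimia = noisy(status_at("bulimia", w), sv["bulimia"], pv["bulimia"]),
      binge_eating = noisy(status_at("binge_eating", w),
                           sv["binge_eating"], pv["binge_eating"]),
      purging = noisy(status_at("purging", w), sv["purging"], pv["purging"]),
      self_harm = noisy(status_at("self_harm", w), sv["self_harm"],
                        pv["self_harm"]),
      cannabis = noisy(status_at("cannabis", w), sv["cannabis"],
                       pv["cannabis"]),
      sr_diagnosis = noisy(status_at("sr_diagnosis", w),
                           sv["sr_diagnosis"], pv["sr_diagnosis"])
    )
    # eating reports must stay mutually consistent after noise
    report[[w]]$binge_eating <- report[[w]]$binge_eating &
      !report[[w]]$bulimia
    report[[w]]$purging <- report[[w]]$purging & !report[[w]]$bulimia &
      !report[[w]]$binge_eating
  }

  # current-disorder probabilities: wave 2 risk is the configured ratio
  # times the participant's own wave-1 risk
  current <- list()
  for (sc in names(cfg$current)) {
    pars <- cfg$current[[sc]]
    lp <- pars["age_slope"] * (age1 - 65) / 10 + log(pars["sex_or"]) * female
    a <- .solve_intercept(lp, pars["base"])
    p1 <- stats::plogis(a + lp)
    p2 <- pmin(pars["wave2_ratio"] * p1, 0.95)
    current[[sc]] <- list(MHQ1 = .rbern(N, p1), MHQ2 = .rbern(N, p2),
                          p1 = p1, p2 = p2)
  }

  ctx <- list(cfg = cfg, dict = dict, N = N, pid = pid, female = female,
              age1 = age1, age2 = age2, lat = lat, onsets = onsets,
              report = report, current = current, height_cm = height_cm)

  mhq1 <- .emit_wave(ctx, which(in_mhq1), "MHQ1")
  mhq2 <- .emit_wave(ctx, which(in_mhq2), "MHQ2")

  baseline <- tibble::tibble(
    pid = pid,
    sex = ifelse(female, "female", "male"),
    birth_year = birth_year, birth_month = birth_month,
    ethnicity = sample(c("White", "Black", "Asian", "Chinese", "Mixed",
                         "Other", "Missing"), N, replace = TRUE,
                       prob = c(0.968, 0.007, 0.009, 0.002, 0.005, 0.005,
                                0.004)),
    townsend = round(stats::rnorm(N, -1.5, 3), 2),
    degree_educated = .rbern(N, 0.44),
    rents_home = .rbern(N, 0.05),
    longstanding_illness = .rbern(N, 0.26),
    smoker = .rbern(N, 0.07),
    physically_active = .rbern(N, 0.37),
    neuroticism_score = pmin(pmax(round(stats::rnorm(N, 3.9, 3.2)), 0), 12),
    height_cm = height_cm
  )

  truth <- tibble::tibble(
    pid = pid, in_mhq1 = in_mhq1, in_mhq2 = in_mhq2,
    sex = baseline$sex, age_mhq1 = age1, age_mhq2 = age2,
    dep_onset_year = onsets$depression,
    bipolar_onset_year = onsets$bipolar,
    panic_onset_year = onsets$panic_disorder,
    sh_onset_year = onsets$self_harm,
    cannabis_onset_year = onsets$cannabis
  )
  for (w in c("MHQ1", "MHQ2")) {
    sfx <- tolower(w)
    truth[[paste0("lifetime_depression_", sfx)]] <- status_at("depression", w)
    truth[[paste0("bipolar_i_", sfx)]] <- status_at("bipolar", w)
    truth[[paste0("self_harm_ever_", sfx)]] <- status_at("self_harm", w)
    truth[[paste0("suicide_attempt_ever_", sfx)]] <-
      status_at("self_harm", w) & lat$suicide_intent
    truth[[paste0("cannabis_ever_", sfx)]] <- status_at("cannabis", w)
    truth[[paste0("cannabis_daily_ever_", sfx)]] <-
      status_at("cannabis", w) & lat$cannabis_daily
    truth[[paste0("any_sr_diagnosis_", sfx)]] <- status_at("sr_diagnosis", w)
    truth[[paste0("melancholic_", sfx)]] <-
      status_at("depression", w) & lat$melancholic
    truth[[paste0("atypical_", sfx)]] <-
      status_at("depression", w) & lat$atypical
    for (ph in names(report[[w]])) {
      truth[[paste0("report_", ph, "_", sfx)]] <- report[[w]][[ph]]
    }
    for (sc in names(current)) {
      truth[[paste0("current_", sc, "_", sfx)]] <- current[[sc]][[w]]
    }
  }
  # second-wave-only modules
  truth$panic_attack_ever_mhq2 <- status_at("panic_attack", "MHQ2")
  truth$panic_disorder_mhq2 <- status_at("panic_disorder", "MHQ2")
  truth$anorexia_mhq2 <- lat$anorexia
  truth$bulimia_mhq2 <- lat$bulimia
  truth$binge_eating_mhq2 <- lat$binge_eating
  truth$purging_disorder_mhq2 <- lat$purging
  truth$any_eating_disorder_mhq2 <- lat$anorexia | lat$bulimia |
    lat$binge_eating | lat$purging

  list(
    mhq1 = mhq1, mhq2 = mhq2, baseline = baseline, truth = truth,
    dictionary = dict,
    counts = c(both = sum(in_mhq1 & in_mhq2),
               mhq1_only = sum(in_mhq1 & !in_mhq2),
               mhq2_only = sum(!in_mhq1 & in_mhq2))
  )
}

# ---- item emission ---------------------------------------------------------

# emit criteria-exact item responses for one wave
.emit_wave <- function(ctx, idx, wave) {
  cfg <- ctx$cfg
  dict <- ctx$dict
  n <- length(idx)
  rep_w <- lapply(ctx$report[[wave]], function(v) v[idx])
  lat <- lapply(ctx$lat, function(v) v[idx])
  onsets <- lapply(ctx$onsets, function(v) v[idx])
  age_w <- if (wave == "MHQ1") ctx$age1[idx] else ctx$age2[idx]
  wave_year <- as.integer(cfg$wave_years[[wave]])
  d <- tibble::tibble(pid = ctx$pid[idx])

  onset_item <- function(true_onset, has_gate) {
    # true onset where known; otherwise a plausible year; "don't know" at
    # the configured rate
    span <- pmax(age_w - cfg$onset_age_min, 0L)
    fake_age <- cfg$onset_age_min + floor(stats::runif(n) * (span + 1))
    fake <- wave_year - (age_w - as.integer(fake_age))
    out <- ifelse(is.na(true_onset), fake, true_onset)
    out <- pmin(out, wave_year)
    out[.rbern(n, cfg$onset_unknown_rate)] <- mhq_onset_unknown()
    as.integer(out)
  }

  ## screening: self-reported diagnoses
  pos <- rep_w$sr_diagnosis
  ticks <- cbind(
    dep = lat$sr_tick_dep, bip = lat$sr_tick_bip, anx = lat$sr_tick_anx,
    eat = lat$sr_tick_eat, pan = lat$sr_tick_pan, oth = lat$sr_tick_oth
  )
  ticks[!pos, ] <- FALSE
  # a positive report must tick at least one condition
  need_fix <- pos & rowSums(ticks) == 0
  ticks[need_fix, "oth"] <- TRUE
  d$srdx_none <- as.integer(!pos)
  d$srdx_depression <- as.integer(ticks[, "dep"])
  d$srdx_bipolar <- as.integer(ticks[, "bip"])
  d$srdx_anxiety <- as.integer(ticks[, "anx"])
  d$srdx_eating <- as.integer(ticks[, "eat"])
  d$srdx_other <- as.integer(ticks[, "oth"])
  if (wave == "MHQ1") {
    d$srdx_panic_combined <- as.integer(ticks[, "pan"])
  } else {
    # the split checkboxes: attacks more commonly endorsed than disorder
    pan_att <- ticks[, "pan"] & .rbern(n, 0.85)
    pan_dis <- ticks[, "pan"] & .rbern(n, 0.3)
    pan_att[ticks[, "pan"] & !pan_att & !pan_dis] <- TRUE
    d$srdx_panic_attacks <- as.integer(pan_att)
    d$srdx_panic_disorder <- as.integer(pan_dis)
  }

  ## PHQ-9 from the current-depression truth
  cur_dep <- ctx$current$depression[[wave]][idx]
  phq <- matrix(0L, n, 9)
  phq[cur_dep, 1] <- sample(2:3, sum(cur_dep), replace = TRUE)
  for (j in 2:5) phq[cur_dep, j] <- sample(2:3, sum(cur_dep), replace = TRUE)
  for (j in 6:9) phq[cur_dep, j] <- sample(0:1, sum(cur_dep), replace = TRUE)
  for (j in 1:8) phq[!cur_dep, j] <- sample(0:1, sum(!cur_dep), replace = TRUE)
  phq[!cur_dep, 9] <- sample(0:1, sum(!cur_dep), replace = TRUE,
                             prob = c(0.95, 0.05))
  for (j in 1:9) d[[paste0("phq9_", j)]] <- phq[, j]

  ## lifetime depression module
  dep <- .emit_depression(n, rep_w$depression, lat, onset_item,
                          onsets$depression, wave)
  d <- dplyr::bind_cols(d, dep)

  ## mania
  man <- .emit_mania(n, rep_w$bipolar, onset_item, onsets$bipolar)
  d <- dplyr::bind_cols(d, man)

  ## GAD-7
  cur_anx <- ctx$current$anxiety[[wave]][idx]
  gad <- matrix(0L, n, 7)
  for (j in 1:5) gad[cur_anx, j] <- sample(2:3, sum(cur_anx), replace = TRUE)
  for (j in 6:7) gad[cur_anx, j] <- sample(0:1, sum(cur_anx), replace = TRUE)
  for (j in 1:7) gad[!cur_anx, j] <- sample(0:1, sum(!cur_anx),
                                            replace = TRUE)
  for (j in 1:7) d[[paste0("gad7_", j)]] <- gad[, j]

  ## panic (second wave only)
  if (wave == "MHQ2") {
    attack <- lat$panic_attack | rep_w$panic_disorder
    pan <- .emit_panic(n, attack, rep_w$panic_disorder, onset_item,
                       onsets$panic_disorder)
    d <- dplyr::bind_cols(d, pan)
  }

  ## childhood adversity
  for (j in 1:4) {
    d[[paste0("cts_", j)]] <- sample(0:4, n, replace = TRUE,
                                     prob = c(0.72, 0.15, 0.08, 0.035,
                                              0.015))
  }
  d$cts_loved <- sample(0:4, n, replace = TRUE,
                        prob = c(0.02, 0.05, 0.13, 0.3, 0.5))
  if (wave == "MHQ2") d$adv_adult_ever <- as.integer(.rbern(n, 0.22))

  ## AUDIT from the harmful-alcohol truth
  cur_alc <- ctx$current$alcohol[[wave]][idx]
  aud <- matrix(0L, n, 10)
  for (j in 1:8) aud[cur_alc, j] <- sample(2:3, sum(cur_alc), replace = TRUE)
  aud[cur_alc, 9] <- sample(c(0L, 2L, 4L), sum(cur_alc), replace = TRUE)
  aud[cur_alc, 10] <- sample(c(0L, 2L, 4L), sum(cur_alc), replace = TRUE)
  for (j in 1:3) aud[!cur_alc, j] <- sample(0:2, sum(!cur_alc),
                                            replace = TRUE)
  for (j in 4:8) aud[!cur_alc, j] <- sample(0:1, sum(!cur_alc),
                                            replace = TRUE)
  for (j in 1:10) d[[paste0("audit_", j)]] <- aud[, j]

  ## cannabis
  pos <- rep_w$cannabis
  freq <- integer(n)
  daily <- pos & lat$cannabis_daily
  freq[pos & !daily] <- sample(1:3, sum(pos & !daily), replace = TRUE)
  freq[daily] <- 4L
  d$can_freq <- freq
  d$can_onset_year <- onset_item(onsets$cannabis, pos)

  ## self-harm
  pos <- rep_w$self_harm
  d$sh_ever <- as.integer(pos)
  d$sh_intent <- as.integer(pos & lat$suicide_intent)
  d$sh_onset_year <- onset_item(onsets$self_harm, pos)

  ## eating patterns (second wave only)
  if (wave == "MHQ2") {
    eat <- .emit_eating(n, rep_w, ctx, idx)
    d <- dplyr::bind_cols(d, eat)
  }

  ## social situation and wellbeing
  d$soc_lives_alone <- as.integer(.rbern(n, 0.19))
  d$soc_visits_lt_monthly <- as.integer(.rbern(n, 0.10))
  d$soc_no_weekly_activity <- as.integer(.rbern(n, 0.35))
  if (wave == "MHQ2") {
    for (j in 1:3) {
      d[[paste0("lone_", j)]] <- sample(1:3, n, replace = TRUE,
                                        prob = c(0.6, 0.25, 0.15))
    }
    for (j in 1:6) {
      v <- pmin(pmax(round(stats::rnorm(n, 3.6, 0.9)), 1), 5)
      if (j %in% c(2, 4, 6)) v <- 6L - v
      d[[paste0("brs_", j)]] <- as.integer(v)
    }
  }
  d$vas <- as.integer(pmin(pmax(round(stats::rnorm(n, 82, 15)), 0), 100))

  # order columns as in the dictionary and apply routing
  items <- intersect(wave_items(dict, wave), names(d))
  d <- d[, c("pid", items)]
  d <- apply_skip_logic(d, dict)

  # item missingness: sentinel-style missing answers on asked non-gate items
  parent_items <- unique(unlist(lapply(seq_len(nrow(dict)), function(i) {
    r <- .skip_rule(dict[i, ])
    if (is.null(r)) NULL else names(r)
  })))
  if (cfg$item_missingness_rate > 0) {
    for (col in setdiff(items, parent_items)) {
      v <- d[[col]]
      hit <- .rbern(n, cfg$item_missingness_rate) & !is.na(v) &
        v != mhq_skipped()
      d[[col]][hit] <- NA_integer_
    }
  }

  # module non-completion: a random suffix of modules left blank
  completed <- .rbern(n, cfg$completion_rate)
  if (any(!completed)) {
    mods <- unique(dict$module[dict$item %in% items])
    start <- sample.int(length(mods) - 1L, sum(!completed),
                        replace = TRUE) + 1L
    inc_rows <- which(!completed)
    for (k in seq_along(inc_rows)) {
      blank_items <- dict$item[dict$module %in% mods[start[k]:length(mods)]]
      blank_items <- intersect(blank_items, items)
      for (col in blank_items) d[[col]][inc_rows[k]] <- NA_integer_
    }
  }

  new_responses(d, dict, wave = wave, completed = completed,
                validate = FALSE)
}

.emit_depression <- function(n, pos, lat, onset_item, true_onset, wave) {
  low <- integer(n); anh <- integer(n); imp <- integer(n)
  probes <- matrix(0L, n, 6)
  # violation choice for negative reporters: 1 gate, 2 symptom count,
  # 3 impairment
  viol <- sample.int(3, n, replace = TRUE)
  gate_pass <- pos | viol != 1L

  i <- which(pos)
  if (length(i) > 0) {
    low[i] <- 1L
    anh[i] <- as.integer(.rbern(length(i), 0.6))
    core <- 1L + anh[i]
    t <- sample(5:8, length(i), replace = TRUE)
    need <- pmin(pmax(t - core, 5L - core), 6L)
    probes[i, ] <- .pick_k(length(i), need, 6)
    imp[i] <- sample(2:3, length(i), replace = TRUE)
  }
  j <- which(!pos & viol == 2L)  # too few symptoms
  if (length(j) > 0) {
    low[j] <- as.integer(.rbern(length(j), 0.8))
    anh[j] <- ifelse(low[j] == 1L, as.integer(.rbern(length(j), 0.4)), 1L)
    core <- low[j] + anh[j]
    t <- core + floor(stats::runif(length(j)) * (5L - core))  # core..4
    probes[j, ] <- .pick_k(length(j), as.integer(t - core), 6)
    imp[j] <- sample(2:3, length(j), replace = TRUE)
  }
  k <- which(!pos & viol == 3L)  # impairment rules out
  if (length(k) > 0) {
    low[k] <- 1L
    anh[k] <- as.integer(.rbern(length(k), 0.4))
    core <- 1L + anh[k]
    t <- sample(5:8, length(k), replace = TRUE)
    need <- pmin(pmax(t - core, 5L - core), 6L)
    probes[k, ] <- .pick_k(length(k), need, 6)
    imp[k] <- sample(0:1, length(k), replace = TRUE)
  }

  out <- tibble::tibble(
    dep_screen_low = low, dep_screen_anh = anh,
    dep_sym_tired = probes[, 1], dep_sym_appetite = probes[, 2],
    dep_sym_sleep = probes[, 3], dep_sym_concentration = probes[, 4],
    dep_sym_worthless = probes[, 5], dep_sym_death = probes[, 6],
    dep_impair = imp,
    dep_onset_year = onset_item(true_onset, gate_pass)
  )
  out$dep_sym_tired <- as.integer(out$dep_sym_tired)
  out$dep_sym_appetite <- as.integer(out$dep_sym_appetite)
  out$dep_sym_sleep <- as.integer(out$dep_sym_sleep)
  out$dep_sym_concentration <- as.integer(out$dep_sym_concentration)
  out$dep_sym_worthless <- as.integer(out$dep_sym_worthless)
  out$dep_sym_death <- as.integer(out$dep_sym_death)

  if (wave == "MHQ2") {
    mel <- lat$melancholic
    aty <- lat$atypical
    nonreact <- integer(n); react <- integer(n)
    melc <- matrix(0L, n, 4); atyc <- matrix(0L, n, 4)
    im <- which(mel)
    if (length(im) > 0) {
      nonreact[im] <- 1L
      melc[im, ] <- .pick_k(length(im),
                            2L + stats::rbinom(length(im), 2, 0.5), 4)
    }
    inm <- which(!mel)
    if (length(inm) > 0) {
      g <- .rbern(length(inm), 0.5)
      nonreact[inm] <- as.integer(g)
      melc[inm, ] <- .pick_k(length(inm),
                             ifelse(g, stats::rbinom(length(inm), 1, 0.5),
                                    stats::rbinom(length(inm), 2, 0.35)), 4)
    }
    ia <- which(aty)
    if (length(ia) > 0) {
      react[ia] <- 1L
      atyc[ia, ] <- .pick_k(length(ia),
                            2L + stats::rbinom(length(ia), 2, 0.5), 4)
    }
    ina <- which(!aty)
    if (length(ina) > 0) {
      g <- .rbern(length(ina), 0.5)
      react[ina] <- as.integer(g)
      atyc[ina, ] <- .pick_k(length(ina),
                             ifelse(g, stats::rbinom(length(ina), 1, 0.5),
                                    stats::rbinom(length(ina), 2, 0.35)), 4)
    }
    out$dep_mel_nonreactive <- nonreact
    out$dep_mel_earlywake <- as.integer(melc[, 1])
    out$dep_mel_worsemorning <- as.integer(melc[, 2])
    out$dep_mel_psychomotor <- as.integer(melc[, 3])
    out$dep_mel_guilt <- as.integer(melc[, 4])
    out$dep_aty_reactive <- react
    out$dep_aty_weightgain <- as.integer(atyc[, 1])
    out$dep_aty_hypersomnia <- as.integer(atyc[, 2])
    out$dep_aty_leaden <- as.integer(atyc[, 3])
    out$dep_aty_rejection <- as.integer(atyc[, 4])
    out$dep_med_ever <- as.integer(lat$med_exposed)
    out$dep_med_helped <- as.integer(lat$med_helped)
    out$dep_ther_ever <- as.integer(lat$ther_exposed)
    out$dep_ther_helped <- as.integer(lat$ther_helped)
  }
  out
}

.emit_mania <- function(n, pos, onset_item, true_onset) {
  elation <- integer(n); irrit <- integer(n); dur <- integer(n)
  syms <- matrix(0L, n, 7)
  viol <- sample.int(3, n, replace = TRUE)
  gate_pass <- pos | viol != 1L

  i <- which(pos)
  if (length(i) > 0) {
    elation[i] <- as.integer(.rbern(length(i), 0.7))
    irrit[i] <- ifelse(elation[i] == 1L,
                       as.integer(.rbern(length(i), 0.4)), 1L)
    syms[i, ] <- .pick_k(length(i), sample(3:7, length(i), replace = TRUE), 7)
    dur[i] <- 2L
  }
  j <- which(!pos & viol == 2L)  # too few symptoms
  if (length(j) > 0) {
    elation[j] <- as.integer(.rbern(length(j), 0.7))
    irrit[j] <- ifelse(elation[j] == 1L,
                       as.integer(.rbern(length(j), 0.3)), 1L)
    syms[j, ] <- .pick_k(length(j), sample(0:2, length(j), replace = TRUE), 7)
    dur[j] <- sample(0:2, length(j), replace = TRUE)
  }
  k <- which(!pos & viol == 3L)  # episode too short
  if (length(k) > 0) {
    elation[k] <- as.integer(.rbern(length(k), 0.7))
    irrit[k] <- ifelse(elation[k] == 1L,
                       as.integer(.rbern(length(k), 0.3)), 1L)
    syms[k, ] <- .pick_k(length(k), sample(3:7, length(k), replace = TRUE), 7)
    dur[k] <- sample(0:1, length(k), replace = TRUE)
  }
  out <- tibble::tibble(
    man_elation = elation, man_irrit = irrit
  )
  for (m in 1:7) {
    out[[paste0("man_sym_", c("active", "talk", "racing", "sleep",
                              "distract", "confid", "risky")[m])]] <-
      as.integer(syms[, m])
  }
  out$man_duration <- dur
  out$man_onset_year <- onset_item(true_onset, gate_pass)
  out
}

.emit_panic <- function(n, attack, disorder, onset_item, true_onset) {
  gate <- integer(n); rec <- integer(n); unex <- integer(n)
  worry <- integer(n)
  syms <- matrix(0L, n, 13)

  i <- which(disorder)
  if (length(i) > 0) {
    gate[i] <- 1L
    syms[i, ] <- .pick_k(length(i), sample(4:13, length(i), replace = TRUE),
                         13)
    rec[i] <- 1L; unex[i] <- 1L; worry[i] <- 1L
  }
  j <- which(attack & !disorder)
  if (length(j) > 0) {
    gate[j] <- 1L
    syms[j, ] <- .pick_k(length(j), sample(4:13, length(j), replace = TRUE),
                         13)
    v <- sample.int(3, length(j), replace = TRUE)
    rec[j] <- ifelse(v == 1L, 0L, as.integer(.rbern(length(j), 0.6)))
    unex[j] <- ifelse(v == 2L, 0L, as.integer(.rbern(length(j), 0.6)))
    worry[j] <- ifelse(v == 3L, 0L, as.integer(.rbern(length(j), 0.6)))
  }
  k <- which(!attack & !disorder)
  if (length(k) > 0) {
    v <- .rbern(length(k), 0.8)  # mostly screened out at the gate
    gate[k] <- as.integer(!v)
    low <- which(!v)
    if (length(low) > 0) {
      syms[k[low], ] <- .pick_k(length(low),
                                sample(0:3, length(low), replace = TRUE), 13)
      rec[k[low]] <- as.integer(.rbern(length(low), 0.3))
      unex[k[low]] <- as.integer(.rbern(length(low), 0.3))
      worry[k[low]] <- as.integer(.rbern(length(low), 0.3))
    }
  }
  out <- tibble::tibble(pan_gate = gate)
  for (m in 1:13) out[[paste0("pan_sym_", m)]] <- as.integer(syms[, m])
  out$pan_recurrent <- rec
  out$pan_unexpected <- unex
  out$pan_worry_month <- worry
  out$pan_onset_year <- onset_item(true_onset, gate == 1L)
  out
}

.emit_eating <- function(n, rep_w, ctx, idx) {
  ano <- rep_w$anorexia
  bul <- rep_w$bulimia
  bin <- rep_w$binge_eating
  pur <- rep_w$purging

  # lowest adult BMI: safely below/above the threshold per report
  bmi <- ifelse(ano, stats::runif(n, 14, 18.2), stats::runif(n, 19.5, 35))
  # anorexia-negative violation paths for latent positives that report
  # negative: a share keep low weight but fail a cognitive criterion
  fear <- integer(n); prevent <- integer(n); body <- integer(n)
  i <- which(ano)
  if (length(i) > 0) {
    fear[i] <- as.integer(.rbern(length(i), 0.8))
    prevent[i] <- ifelse(fear[i] == 1L,
                         as.integer(.rbern(length(i), 0.5)), 1L)
    body[i] <- 1L
  }
  j <- which(!ano)
  if (length(j) > 0) {
    fear[j] <- as.integer(.rbern(length(j), 0.12))
    prevent[j] <- as.integer(.rbern(length(j), 0.08))
    body[j] <- as.integer(.rbern(length(j), 0.15))
  }

  binge <- integer(n); bw <- integer(n); distress <- integer(n)
  axonly <- integer(n); comp <- integer(n); cw <- integer(n)
  purge <- integer(n)
  i <- which(bul)
  if (length(i) > 0) {
    binge[i] <- 1L; bw[i] <- 1L
    distress[i] <- as.integer(.rbern(length(i), 0.7))
    axonly[i] <- 0L
    comp[i] <- 1L; cw[i] <- 1L
    purge[i] <- as.integer(.rbern(length(i), 0.6))
  }
  i <- which(bin)
  if (length(i) > 0) {
    binge[i] <- 1L; bw[i] <- 1L; distress[i] <- 1L; axonly[i] <- 0L
    has_comp <- .rbern(length(i), 0.5)
    comp[i] <- as.integer(has_comp)
    cw[i] <- 0L  # compensation, if any, is not regular
    purge[i] <- as.integer(has_comp & .rbern(length(i), 0.3))
  }
  i <- which(pur)
  if (length(i) > 0) {
    comp[i] <- 1L; cw[i] <- 1L; purge[i] <- 1L
    binge[i] <- 0L
  }
  i <- which(!bul & !bin & !pur)
  if (length(i) > 0) {
    b <- .rbern(length(i), 0.05)
    binge[i] <- as.integer(b)
    bw[i] <- 0L  # any binges are not regular
    distress[i] <- as.integer(.rbern(length(i), 0.3))
    axonly[i] <- as.integer(.rbern(length(i), 0.1))
    cmp <- .rbern(length(i), 0.05)
    comp[i] <- as.integer(cmp)
    cw[i] <- 0L
    purge[i] <- as.integer(cmp & .rbern(length(i), 0.3))
  }

  # weight from the target BMI at the participant's baseline height
  height_cm <- ctx$height_cm
  tibble::tibble(
    ed_lowest_weight_kg = as.integer(pmin(pmax(
      round(bmi * (height_cm[idx] / 100)^2), 25), 200)),
    ed_fear = fear, ed_prevent = prevent, ed_bodyimage = body,
    ed_binge = binge, ed_binge_weekly_3m = bw, ed_distress = distress,
    ed_binge_anorexia_only = axonly,
    ed_comp = comp, ed_comp_weekly_3m = cw, ed_comp_purging = purge
  )
}
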