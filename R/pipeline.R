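#' Run the full analysis pipeline on a synthetic cohort
#'
#' One-command end-to-end demonstration: simulate a two-wave cohort, write
#' the raw tables, reload them through the validating loader, score the
#' instruments, derive the phenotype profiles for both waves, and produce
#' the standard outputs -- a stratified characteristics table, comorbidity
#' overlap counts, age/sex/wave-stratified current-disorder proportions
#' with relative risks, the cross-wave agreement summary, and per-phenotype
#' prevalence figures. A run record (resolved configuration, seed, package
#' version, partition counts) is written as JSON so any artefact can be
#' reproduced.
#'
#' @param outdir Output directory (created if needed).
#' @param config Cohort configuration from [cohort_config()].
#' @param seed RNG seed (overrides `config$seed`).
#' @param cutoff_year Onset-adjudication cutoff.
#' @param write_plots Write the per-phenotype prevalence figures.
#' @return Invisibly, a list with every computed table.
#' @export
run_pipeline <- function(outdir, config = cohort_config(),
                         seed = config$seed, cutoff_year = 2016L,
                         write_plots = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config, seed = seed)

  # write and reload through the validating loader
  write_dictionary(sim$dictionary, file.path(outdir, "dictionary.yaml"))
  write_responses(sim$mhq1, file.path(outdir, "mhq1.csv"))
  write_responses(sim$mhq2, file.path(outdir, "mhq2.csv"))
  utils::write.csv(sim$baseline, file.path(outdir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(outdir, "truth.csv"),
                   row.names = FALSE)
  mhq1 <- load_responses(file.path(outdir, "mhq1.csv"), sim$dictionary,
                         wave = "MHQ1")
  mhq2 <- load_responses(file.path(outdir, "mhq2.csv"), sim$dictionary,
                         wave = "MHQ2")
  cohort <- merge_waves(mhq1, mhq2)

  scores1 <- score_instruments(mhq1)
  scores2 <- score_instruments(mhq2)
  profile1 <- derive_phenotypes(mhq1, baseline = sim$baseline)
  profile2 <- derive_phenotypes(mhq2, baseline = sim$baseline)
  utils::write.csv(profile2, file.path(outdir, "profile_mhq2.csv"),
                   row.names = FALSE)

  # analysis restricted to completers; longitudinal parts to both-wave ids
  p2c <- profile2[profile2$completed, ]
  table3 <- characteristic_table(sim$baseline, profile2, scores2,
                                 completion_date = c(
                                   as.integer(config$wave_years[["MHQ2"]]),
                                   11L))
  utils::write.csv(table3, file.path(outdir, "characteristics.csv"),
                   row.names = FALSE)
  overlaps <- comorbidity_overlaps(p2c)
  utils::write.csv(overlaps, file.path(outdir, "comorbidity.csv"),
                   row.names = FALSE)

  both <- cohort$both
  long <- dplyr::bind_rows(
    .wave_status_frame(profile1, scores1, sim$truth, "MHQ1", both),
    .wave_status_frame(profile2, scores2, sim$truth, "MHQ2", both)
  )
  strata <- stratified_proportions(long)
  rr <- relative_risk(strata)
  utils::write.csv(strata, file.path(outdir, "strata.csv"),
                   row.names = FALSE)
  utils::write.csv(rr, file.path(outdir, "relative_risk.csv"),
                   row.names = FALSE)

  b1 <- profile1[profile1$pid %in% both & profile1$completed, ]
  b2 <- profile2[profile2$pid %in% both & profile2$completed, ]
  table4 <- agreement_summary(b1, b2, cutoff_year = cutoff_year)
  utils::write.csv(table4, file.path(outdir, "agreement.csv"),
                   row.names = FALSE)

  if (write_plots) {
    for (ph in unique(strata$phenotype)) {
      p <- plot_current_prevalence(strata[strata$phenotype == ph, ])
      ggplot2::ggsave(file.path(outdir, paste0("prevalence_", ph, ".pdf")),
                      p, width = 7, height = 5)
    }
  }

  record <- list(
    package_version = as.character(utils::packageVersion("mhqtools")),
    seed = seed,
    cutoff_year = cutoff_year,
    counts = as.list(sim$counts),
    config = .serialisable_config(config)
  )
  jsonlite::write_json(record, file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, scores1 = scores1, scores2 = scores2,
    profile1 = profile1, profile2 = profile2, table3 = table3,
    overlaps = overlaps, strata = strata, relative_risk = rr,
    table4 = table4, truth = sim$truth, baseline = sim$baseline,
    record = record
  ))
}

# one row per participant-wave with ages at that wave and current statuses
.wave_status_frame <- function(profile, scores, truth, wave, both_ids) {
  keep <- profile$pid %in% both_ids & profile$completed
  p <- profile[keep, ]
  tr <- truth[match(p$pid, truth$pid), ]
  age_w <- if (wave == "MHQ1") tr$age_mhq1 else tr$age_mhq2
  tibble::tibble(
    pid = p$pid, wave = wave, sex = tr$sex,
    age = age_w,
    current_depression = p$current_depression_phq9,
    current_anxiety = p$current_anxiety_gad7,
    harmful_alcohol = p$harmful_alcohol
  )
}

.serialisable_config <- function(cfg) {
  out <- unclass(cfg)
  out$sensitivity <- lapply(out$sensitivity, as.list)
  out$specificity <- lapply(out$specificity, as.list)
  out$prevalence <- as.list(out$prevalence)
  out
}
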