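#' Seven-year age bins for cross-wave comparison
#'
#' Bins of width seven anchored at 45 (45-51, 52-58, 59-65, 66-72, 73-79,
#' 80-86, ...), chosen to match the approximate interval between the two
#' questionnaire waves so that a cohort member typically moves one bin
#' between waves, and so that same-age strata (e.g. 73-79) can be compared
#' across waves.
#'
#' @param age Integer ages, all at least 45.
#' @return Character bin labels like `"73-79"`.
#' @export
seven_year_bins <- function(age) {
  if (any(age < 45, na.rm = TRUE)) {
    stop("age below the 45+ analytic range", call. = FALSE)
  }
  lo <- 45L + 7L * ((as.integer(age) - 45L) %/% 7L)
  sprintf("%d-%d", lo, lo + 6L)
}

#' Age/sex/wave-stratified proportions of current disorder
#'
#' One estimate per wave, sex, seven-year age bin and status column: the
#' number positive, stratum size and proportion. Age is at completion of
#' the relevant wave, so participants can change bins between waves.
#' Participants with a missing status are excluded from that status's
#' strata; empty strata are omitted.
#'
#' @param data Long tibble, one row per participant-wave: columns `pid`,
#'   `wave`, `sex`, `age`, plus one logical column per status.
#' @param statuses Character vector of status column names.
#' @return Tibble with `wave`, `sex`, `age_bin`, `phenotype`, `n`,
#'   `n_positive`, `proportion`. Rows younger than the 45+ analytic range
#'   are excluded; their number is reported in the `n_below_range`
#'   attribute.
#' @export
stratified_proportions <- function(data,
                                   statuses = c("current_depression",
                                                "current_anxiety",
                                                "harmful_alcohol")) {
  below <- sum(data$age < 45, na.rm = TRUE)
  # pooled (whole-cohort) totals are taken before the 45+ bin restriction,
  # so the overall relative risk reflects every both-wave completer
  pooled <- lapply(statuses, function(st) {
    d <- data[!is.na(data[[st]]), , drop = FALSE]
    d$.status <- d[[st]]
    res <- dplyr::summarise(
      dplyr::group_by(d, .data$wave),
      n = dplyr::n(), n_positive = sum(.data$.status), .groups = "drop"
    )
    res$phenotype <- st
    res
  })
  pooled <- dplyr::bind_rows(pooled)

  data <- data[!is.na(data$age) & data$age >= 45, , drop = FALSE]
  data$age_bin <- seven_year_bins(data$age)
  out <- lapply(statuses, function(st) {
    d <- data[!is.na(data[[st]]), , drop = FALSE]
    d$.status <- d[[st]]
    res <- dplyr::summarise(
      dplyr::group_by(d, .data$wave, .data$sex, .data$age_bin),
      n = dplyr::n(),
      n_positive = sum(.data$.status),
      .groups = "drop"
    )
    res$phenotype <- st
    res
  })
  out <- dplyr::bind_rows(out)
  out$proportion <- out$n_positive / out$n
  out <- out[, c("wave", "sex", "age_bin", "phenotype", "n", "n_positive",
                 "proportion")]
  attr(out, "n_below_range") <- below
  attr(out, "pooled") <- pooled
  out
}

#' Relative risk of current disorder between waves
#'
#' Treats the proportion positive as the risk and divides the second-wave
#' risk by the first-wave risk, within each sex-by-age-bin stratum and for
#' the cohort overall (pooled, unstratified proportions). Strata with a
#' zero first-wave proportion yield an undefined (NA) relative risk.
#'
#' @param strata Output of [stratified_proportions()]; the two waves must
#'   be labelled `"MHQ1"` and `"MHQ2"`.
#' @return Tibble with `phenotype`, `sex` (`"overall"` for the pooled row),
#'   `age_bin` (`"overall"`), `rr`, `n_mhq1`, `n_mhq2`, `p_mhq1`, `p_mhq2`.
#' @export
relative_risk <- function(strata) {
  w1 <- strata[strata$wave == "MHQ1", ]
  w2 <- strata[strata$wave == "MHQ2", ]
  per <- dplyr::inner_join(
    w1, w2, by = c("sex", "age_bin", "phenotype"), suffix = c("_mhq1", "_mhq2")
  )
  per_out <- tibble::tibble(
    phenotype = per$phenotype, sex = per$sex, age_bin = per$age_bin,
    rr = ifelse(per$proportion_mhq1 > 0,
                per$proportion_mhq2 / per$proportion_mhq1, NA_real_),
    n_mhq1 = per$n_mhq1, n_mhq2 = per$n_mhq2,
    p_mhq1 = per$proportion_mhq1, p_mhq2 = per$proportion_mhq2
  )
  totals <- attr(strata, "pooled")
  pooled <- lapply(unique(strata$phenotype), function(ph) {
    if (!is.null(totals)) {
      s1 <- totals[totals$phenotype == ph & totals$wave == "MHQ1", ]
      s2 <- totals[totals$phenotype == ph & totals$wave == "MHQ2", ]
    } else {
      s1 <- w1[w1$phenotype == ph, ]
      s2 <- w2[w2$phenotype == ph, ]
    }
    p1 <- sum(s1$n_positive) / sum(s1$n)
    p2 <- sum(s2$n_positive) / sum(s2$n)
    tibble::tibble(
      phenotype = ph, sex = "overall", age_bin = "overall",
      rr = ifelse(p1 > 0, p2 / p1, NA_real_),
      n_mhq1 = sum(s1$n), n_mhq2 = sum(s2$n), p_mhq1 = p1, p_mhq2 = p2
    )
  })
  dplyr::bind_rows(c(list(per_out), pooled))
}

#' Construct a 2x2 cross-wave contingency table
#'
#' @param a Positive at both waves.
#' @param b Positive at the first wave only.
#' @param c Positive at the second wave only.
#' @param d Negative at both waves.
#' @param phenotype Optional label.
#' @return An `mhq_contingency` object.
#' @export
new_contingency <- function(a, b, c, d, phenotype = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  structure(
    list(phenotype = phenotype, a = a, b = b, c = c, d = d,
         n = a + b + c + d),
    class = "mhq_contingency"
  )
}

#' @export
print.mhq_contingency <- function(x, ...) {
  cat(sprintf(
    "<mhq_contingency> %s: ++ %d, +- %d, -+ %d, -- %d (N = %d)\n",
    ifelse(is.na(x$phenotype), "(unnamed)", x$phenotype),
    x$a, x$b, x$c, x$d, x$n
  ))
  invisible(x)
}

#' Cross-tabulate a lifetime phenotype across waves
#'
#' Counts participants positive/negative at each wave among those with a
#' non-missing status at both waves; the excluded (missing-either) tally is
#' reported alongside. Also collects the second-wave onset years of the
#' wave-2-only positives for onset adjudication.
#'
#' @param profile1,profile2 Phenotype profiles for the two waves (from
#'   [derive_phenotypes()]), restricted by the caller or not: only ids
#'   present in both are used.
#' @param phenotype Profile column name.
#' @param onset_column Optional onset-year column in `profile2`; default
#'   chosen automatically for the known lifetime phenotypes.
#' @return An `mhq_contingency` with extra fields `n_excluded` and
#'   `c_onsets` (onset years of the second-wave-only positives; -1 =
#'   reported unknown, NA = missing).
#' @export
build_contingency <- function(profile1, profile2, phenotype,
                              onset_column = NULL) {
  if (is.null(onset_column)) {
    onset_column <- switch(
      phenotype,
      lifetime_depression = "dep_onset_year",
      bipolar_i = "bipolar_onset_year",
      self_harm_ever = "sh_onset_year",
      cannabis_ever = "cannabis_onset_year",
      NA_character_
    )
  }
  common <- intersect(profile1$pid, profile2$pid)
  p1 <- profile1[match(common, profile1$pid), ]
  p2 <- profile2[match(common, profile2$pid), ]
  s1 <- p1[[phenotype]]
  s2 <- p2[[phenotype]]
  ok <- !is.na(s1) & !is.na(s2)
  res <- new_contingency(
    a = sum(s1[ok] & s2[ok]),
    b = sum(s1[ok] & !s2[ok]),
    c = sum(!s1[ok] & s2[ok]),
    d = sum(!s1[ok] & !s2[ok]),
    phenotype = phenotype
  )
  res$n_excluded <- sum(!ok)
  res$c_onsets <- if (!is.na(onset_column) && onset_column %in% names(p2)) {
    p2[[onset_column]][ok & !s1 & s2]
  } else {
    NULL
  }
  res
}

#' Percent agreement of a 2x2 cross-wave table
#'
#' The proportion whose status agrees at the two waves (both positive or
#' both negative), formatted with the publication percent rule.
#'
#' @param t An `mhq_contingency`.
#' @return List with `proportion` and `formatted`.
#' @export
percent_agreement <- function(t) {
  p <- (t$a + t$d) / t$n
  list(proportion = p, formatted = format_percent(t$a + t$d, t$n))
}

#' Cohen's kappa for a 2x2 cross-wave table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with
#' p_o = (a+d)/N and p_e = p1 p2 + (1-p1)(1-p2), where p1 and p2 are the
#' positive marginals of the two waves.
#'
#' @param t An `mhq_contingency`.
#' @return Numeric kappa (report to two decimals, half-up, via
#'   [round_half_up()]).
#' @export
cohens_kappa <- function(t) {
  p_o <- (t$a + t$d) / t$n
  p1 <- (t$a + t$b) / t$n
  p2 <- (t$a + t$c) / t$n
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  if (p_e == 1) {
    stop("degenerate marginals: chance agreement is 1, kappa undefined",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Onset adjudication of new second-wave positives
#'
#' Of the participants positive at the second wave only, counts those whose
#' reported onset year is strictly before the cutoff (approximate date of
#' the first wave): these could have been detected then. Onsets reported as
#' "don't know" (code -1) and missing onsets are grouped with the later
#' onsets, attributing as much discordance as possible to test-retest
#' variability rather than new onset.
#'
#' @param onsets Integer onset years of the second-wave-only positives
#'   (-1 = unknown, NA = missing).
#' @param cutoff_year First-wave year (default 2016).
#' @return List with `n_early`, `n_total`, `proportion` and `formatted`
#'   (always one decimal place, as printed for this column).
#' @export
onset_adjudication <- function(onsets, cutoff_year = 2016L) {
  n_total <- length(onsets)
  n_early <- sum(!is.na(onsets) & onsets > 0 & onsets < cutoff_year)
  p <- if (n_total > 0) n_early / n_total else NA_real_
  list(
    n_early = n_early, n_total = n_total, proportion = p,
    formatted = if (n_total > 0) {
      sprintf("%.1f%%", round_half_up(100 * p, 1))
    } else {
      NA_character_
    }
  )
}

#' Test-retest agreement summary across lifetime phenotypes
#'
#' One row per phenotype: the four contingency cells, percent agreement,
#' kappa (two decimals) and -- where an onset item exists -- the
#' onset-adjudication fraction of the new second-wave positives.
#'
#' @param profile1,profile2 Phenotype profiles for the two waves.
#' @param phenotypes Profile columns to compare.
#' @param cutoff_year Onset adjudication cutoff.
#' @return Tibble with `phenotype`, `a`, `b`, `c`, `d`, `n`, `n_excluded`,
#'   `agreement`, `agreement_formatted`, `kappa`, `kappa_2dp`,
#'   `onset_early`, `onset_total`, `onset_formatted`.
#' @export
agreement_summary <- function(profile1, profile2,
                              phenotypes = c("lifetime_depression",
                                             "bipolar_i", "self_harm_ever",
                                             "cannabis_ever",
                                             "any_sr_diagnosis"),
                              cutoff_year = 2016L) {
  rows <- lapply(phenotypes, function(ph) {
    t <- build_contingency(profile1, profile2, ph)
    pa <- percent_agreement(t)
    k <- cohens_kappa(t)
    adj <- if (!is.null(t$c_onsets)) {
      onset_adjudication(t$c_onsets, cutoff_year)
    } else {
      list(n_early = NA_integer_, n_total = NA_integer_,
           formatted = NA_character_)
    }
    tibble::tibble(
      phenotype = ph, a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
      n_excluded = t$n_excluded,
      agreement = pa$proportion, agreement_formatted = pa$formatted,
      kappa = k, kappa_2dp = round_half_up(k, 2),
      onset_early = adj$n_early, onset_total = adj$n_total,
      onset_formatted = adj$formatted
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot current-disorder proportions by age, sex and wave
#'
#' Line chart of the stratified proportions: age bin on the x axis,
#' proportion positive on the y axis, one line per sex-wave combination.
#'
#' @param strata Output of [stratified_proportions()], one phenotype.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_current_prevalence <- function(strata, title = unique(strata$phenotype)) {
  strata$group <- interaction(strata$sex, strata$wave, sep = " / ")
  ggplot2::ggplot(
    strata,
    ggplot2::aes(x = .data$age_bin, y = .data$proportion,
                 colour = .data$group, group = .data$group)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age group at completion", y = "Proportion positive",
                  colour = "sex / wave", title = title) +
    ggplot2::theme_minimal()
}
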