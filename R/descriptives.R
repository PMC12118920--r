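#' Round half-up at a given number of decimals
#'
#' Base `round()` rounds half to even; displayed percentages here round
#' half away from zero at the printed precision.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a percentage with the publication rounding rule
#'
#' Percentages are rendered in whole points unless under 10 percent, when
#' one decimal place is used. The branch is decided on the unrounded value;
#' rounding is half-up.
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return Character vector like `"18%"` or `"4.0%"`.
#' @export
format_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("format_percent: denominator must be positive", call. = FALSE)
  }
  p <- 100 * numerator / denominator
  ifelse(p >= 10,
         sprintf("%d%%", as.integer(round_half_up(p, 0))),
         sprintf("%.1f%%", round_half_up(p, 1)))
}

#' Merge small table rows for confidentiality
#'
#' Rows of a labelled count table whose any displayed cell holds between 1
#' and `threshold - 1` participants are pooled into a single `"[Combined]"`
#' row. Pooling is minimal and deterministic: offending rows are pooled in
#' label order, and if the pooled row itself still holds an offending cell,
#' further rows are added in order until it does not (or no rows remain).
#' Zero cells are not disclosive and do not trigger pooling.
#'
#' @param rows Data frame: a `label` column plus one or more count columns.
#' @param threshold Minimum publishable cell size (default 10).
#' @param combined_label Label of the pooled row.
#' @return Data frame with the same count columns; pooled rows replaced by
#'   one combined row (placed last). Attribute `merged_labels` lists the
#'   pooled labels.
#' @export
small_cell_merge <- function(rows, threshold = 10,
                             combined_label = "[Combined]") {
  counts <- rows[, setdiff(names(rows), "label"), drop = FALSE]
  offending <- function(m) {
    any(m >= 1 & m <= threshold - 1, na.rm = TRUE)
  }
  bad <- vapply(seq_len(nrow(rows)),
                function(i) offending(as.numeric(counts[i, ])), logical(1))
  if (!any(bad)) {
    attr(rows, "merged_labels") <- character(0)
    return(rows)
  }
  pool <- which(bad)
  keep <- which(!bad)
  pooled <- colSums(counts[pool, , drop = FALSE], na.rm = TRUE)
  # extend the pool (in label order) while the combined row is itself small
  while (offending(pooled) && length(keep) > 0) {
    nxt <- keep[1]
    keep <- keep[-1]
    pool <- c(pool, nxt)
    pooled <- pooled + as.numeric(counts[nxt, ])
  }
  out <- rows[sort(keep), , drop = FALSE]
  comb <- rows[1, , drop = FALSE]
  comb$label <- combined_label
  comb[, names(counts)] <- as.list(pooled)
  out <- rbind(out, comb)
  rownames(out) <- NULL
  attr(out, "merged_labels") <- rows$label[sort(pool)]
  out
}

#' Age in completed years at an event
#'
#' Floor age from birth year/month to event year/month: no rounding up in
#' the birthday month. In reference-date mode the same arithmetic applies
#' to every participant (including, for a whole-cohort description, those
#' who died before the reference date).
#'
#' @param birth_year,birth_month Integers.
#' @param event_year,event_month Integers (the questionnaire completion or
#'   the reference date).
#' @return Integer ages.
#' @export
age_at_event <- function(birth_year, birth_month, event_year, event_month) {
  as.integer(event_year - birth_year - as.integer(event_month < birth_month))
}

#' Ten-year display age band
#'
#' Bands 45-54, 55-64, 65-74, 75-84 and >84 for descriptive tables; with
#' `collapse_oldest = TRUE` the last two merge to 75+ (used when stratifying
#' rare phenotypes).
#'
#' @param age Integer ages.
#' @param collapse_oldest Merge 75-84 and >84 into "75+".
#' @return Character band labels.
#' @export
age_band <- function(age, collapse_oldest = FALSE) {
  band <- ifelse(age < 45, "<45",
          ifelse(age <= 54, "45-54",
          ifelse(age <= 64, "55-64",
          ifelse(age <= 74, "65-74",
          ifelse(age <= 84, "75-84", ">84")))))
  if (collapse_oldest) {
    band[band %in% c("75-84", ">84")] <- "75+"
  }
  band
}

# median (IQR) with the lower-interpolation (inverse-ECDF) convention so
# integer scores print integer quartiles
.median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("NA")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}

.mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("NA")
  sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
}

#' Stratified descriptive characteristics table
#'
#' Builds a long-format table in the style of a cohort-description paper:
#' one block per characteristic (age bands, sex, ethnicity, social factors,
#' adversity, resilience, isolation, plus median/IQR and mean/SD rows for
#' scores), one column group per phenotype (overall, no-lifetime-criteria,
#' then each requested phenotype). Cell percentages use the publication
#' rounding rule; categorical blocks are small-cell merged so no displayed
#' count falls in 1..`suppress_threshold - 1`, with ethnicity pooling all
#' non-White categories plus Missing when any one offends. Columns whose
#' phenotype has no positive cases are dropped with a note.
#'
#' @param baseline Tibble with `pid`, `sex`, `birth_year`, `birth_month`,
#'   `ethnicity`, `townsend`, `degree_educated`, `rents_home`,
#'   `longstanding_illness`, `smoker`, `physically_active`,
#'   `neuroticism_score`.
#' @param profile Phenotype profile from [derive_phenotypes()] (second
#'   wave), including `cts_any`-style inputs via `scores`.
#' @param scores Instrument scores from [score_instruments()] (second wave).
#' @param phenotypes Character vector of profile columns to stratify by.
#' @param completion_date `c(year, month)` used for age at completion.
#' @param suppress_threshold Minimum publishable cell size.
#' @return Tibble with columns `characteristic`, `level`, `column`, `n`,
#'   `value` (formatted percent or summary), `merged` (logical).
#' @export
characteristic_table <- function(baseline, profile, scores,
                                 phenotypes = c("lifetime_depression",
                                                "panic_disorder",
                                                "any_eating_disorder",
                                                "bipolar_i"),
                                 completion_date = c(2022L, 11L),
                                 suppress_threshold = 10) {
  df <- dplyr::inner_join(profile, baseline, by = "pid")
  df <- dplyr::inner_join(df, scores, by = "pid")
  df <- df[df$completed, , drop = FALSE]
  df$age <- age_at_event(df$birth_year, df$birth_month,
                         completion_date[1], completion_date[2])
  df$age_group <- age_band(df$age, collapse_oldest = TRUE)
  df$deprived <- df$townsend >= 2

  cols <- list(Overall = rep(TRUE, nrow(df)))
  cols[["No lifetime criteria"]] <- .is_false(df$any_lifetime_disorder)
  dropped <- character(0)
  for (ph in phenotypes) {
    mask <- .is_true(df[[ph]])
    if (sum(mask) == 0) {
      dropped <- c(dropped, ph)
    } else {
      cols[[ph]] <- mask
    }
  }

  cat_block <- function(charname, values, levels) {
    counts <- data.frame(label = levels, stringsAsFactors = FALSE)
    for (cn in names(cols)) {
      counts[[cn]] <- vapply(levels, function(lv) {
        sum(values == lv & cols[[cn]], na.rm = TRUE)
      }, numeric(1))
    }
    merged <- small_cell_merge(counts, threshold = suppress_threshold)
    was_merged <- length(attr(merged, "merged_labels")) > 0
    out <- list()
    for (cn in names(cols)) {
      denom <- sum(cols[[cn]], na.rm = TRUE)
      out[[cn]] <- tibble::tibble(
        characteristic = charname, level = merged$label, column = cn,
        n = merged[[cn]],
        value = format_percent(merged[[cn]], denom),
        merged = was_merged & merged$label == "[Combined]"
      )
    }
    dplyr::bind_rows(out)
  }

  bin_block <- function(charname, flag) {
    out <- list()
    for (cn in names(cols)) {
      n <- sum(.is_true(flag) & cols[[cn]], na.rm = TRUE)
      denom <- sum(cols[[cn]], na.rm = TRUE)
      suppressed <- n >= 1 & n <= suppress_threshold - 1
      out[[cn]] <- tibble::tibble(
        characteristic = charname, level = "yes", column = cn,
        n = ifelse(suppressed, NA_real_, n),
        value = ifelse(suppressed, "<10", format_percent(max(n, 0), denom)),
        merged = FALSE
      )
    }
    dplyr::bind_rows(out)
  }

  summary_block <- function(charname, values, f) {
    out <- list()
    for (cn in names(cols)) {
      out[[cn]] <- tibble::tibble(
        characteristic = charname, level = "summary", column = cn,
        n = NA_real_, value = f(values[cols[[cn]]]), merged = FALSE
      )
    }
    dplyr::bind_rows(out)
  }

  eth_levels <- c("White", "Black", "Asian", "Chinese", "Mixed", "Other",
                  "Missing")
  # ethnicity rule: if any non-White cell is small, pool all non-White
  # categories plus Missing rather than only the offending one
  eth_counts <- data.frame(label = eth_levels, stringsAsFactors = FALSE)
  for (cn in names(cols)) {
    eth_counts[[cn]] <- vapply(eth_levels, function(lv) {
      sum(df$ethnicity == lv & cols[[cn]], na.rm = TRUE)
    }, numeric(1))
  }
  non_white <- eth_counts$label != "White"
  small <- vapply(seq_len(nrow(eth_counts)), function(i) {
    any(eth_counts[i, -1] >= 1 & eth_counts[i, -1] < suppress_threshold)
  }, logical(1))
  if (any(small & non_white)) {
    pooled <- colSums(eth_counts[non_white, -1, drop = FALSE])
    eth_counts <- rbind(
      eth_counts[!non_white, , drop = FALSE],
      cbind(data.frame(label = "[Combined]", stringsAsFactors = FALSE),
            as.data.frame(as.list(pooled), check.names = FALSE))
    )
  }
  eth_block <- list()
  for (cn in names(cols)) {
    denom <- sum(cols[[cn]], na.rm = TRUE)
    eth_block[[cn]] <- tibble::tibble(
      characteristic = "Ethnicity", level = eth_counts$label, column = cn,
      n = eth_counts[[cn]],
      value = format_percent(eth_counts[[cn]], denom),
      merged = eth_counts$label == "[Combined]"
    )
  }

  # final disclosure-control pass: a cell that stays small even after
  # pooling (possible in sparse phenotype columns) is suppressed outright
  suppress_residual <- function(block) {
    small <- !is.na(block$n) & block$n >= 1 & block$n <= suppress_threshold - 1
    block$value[small] <- "<10"
    block$n[small] <- NA_real_
    block$merged[small] <- TRUE
    block
  }

  res <- dplyr::bind_rows(
    cat_block("Age group", df$age_group,
              c("45-54", "55-64", "65-74", "75+")),
    summary_block("Age, median (IQR)", df$age, .median_iqr),
    cat_block("Sex", df$sex, c("female", "male")),
    dplyr::bind_rows(eth_block),
    bin_block("Degree educated", df$degree_educated),
    bin_block("Resides in deprived area", df$deprived),
    bin_block("Rents home", df$rents_home),
    bin_block("Illness >1y", df$longstanding_illness),
    bin_block("Smoker", df$smoker),
    bin_block("Physically active", df$physically_active),
    bin_block("Childhood adverse experience", df$cts_any),
    bin_block("Adult adverse experience", df$adult_adverse_ever),
    bin_block("Low resilience", df$brs_low),
    bin_block("Social isolation", df$social_isolation),
    summary_block("Loneliness, median (IQR)", df$lone_total, .median_iqr),
    summary_block("Self-rated health, median (IQR)", df$vas, .median_iqr),
    summary_block("Neuroticism, mean (sd)", df$neuroticism_score, .mean_sd)
  )
  res <- suppress_residual(res)
  attr(res, "dropped_columns") <- dropped
  attr(res, "column_totals") <- vapply(cols, sum, numeric(1))
  res
}

#' Comorbidity overlap counts
#'
#' Exact set-intersection counts over a set of binary phenotypes, in the
#' form an UPSET plot consumes: for every non-empty combination, the number
#' of participants positive for exactly that combination (exclusive
#' counts). Participants missing any of the listed phenotypes are excluded
#' and tallied.
#'
#' @param profile Phenotype profile tibble.
#' @param phenotypes Character vector of logical profile columns.
#' @return Tibble with `combination` (e.g. `"lifetime_depression+self_harm_ever"`),
#'   `degree`, `n`. Attributes: `marginals` (named totals per phenotype),
#'   `n_excluded_missing`.
#' @export
comorbidity_overlaps <- function(profile,
                                 phenotypes = c("lifetime_depression",
                                                "panic_disorder",
                                                "any_eating_disorder",
                                                "bipolar_i",
                                                "self_harm_ever")) {
  m <- as.matrix(profile[, phenotypes, drop = FALSE])
  complete <- rowSums(is.na(m)) == 0
  excluded <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  key <- apply(m, 1, function(r) paste(phenotypes[as.logical(r)],
                                       collapse = "+"))
  key <- key[key != ""]
  tab <- table(key)
  out <- tibble::tibble(
    combination = names(tab),
    degree = vapply(strsplit(names(tab), "+", fixed = TRUE), length,
                    integer(1)),
    n = as.integer(tab)
  )
  out <- out[order(-out$n), ]
  marg <- colSums(m)
  storage.mode(marg) <- "integer"
  attr(out, "marginals") <- marg
  attr(out, "n_excluded_missing") <- excluded
  attr(out, "n_total") <- nrow(m)
  out
}
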