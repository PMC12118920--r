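#' Sentinel code for items skipped by routing logic
#'
#' Items that a respondent never saw because a gate ("screener") question
#' routed them past the block are *skipped*, not missing: the questionnaire
#' logic determines their answer (criterion not met). Skipped cells are held
#' as this integer code so that downstream algorithms can treat them as
#' definite negatives while genuinely missing answers stay `NA`.
#'
#' @return Integer scalar, the internal skipped code.
#' @export
mhq_skipped <- function() -9L

#' Onset-year code for "do not know"
#'
#' Respondents may report that they cannot date the onset of a lifetime
#' phenotype. That answer is a real response (not missing) and is carried as
#' this code in onset-year items; onset adjudication groups it with
#' post-cutoff onsets.
#'
#' @return Integer scalar.
#' @export
mhq_onset_unknown <- function() -1L

# default missing-value sentinels; dictionaries may override
.default_sentinels <- c(-818L, -121L)

.onset_year_min <- 1930L
.onset_year_max <- 2023L

# item definition helper: one row per item
.item <- function(item, module, prompt, min, max, extra = "",
                  parents = "", ask = "", waves = "both") {
  data.frame(
    item = item, module = module, prompt = prompt,
    min = as.integer(min), max = as.integer(max), extra = extra,
    parents = parents, ask = ask, waves = waves,
    stringsAsFactors = FALSE
  )
}

.onset_item <- function(item, module, prompt, parents, ask, waves = "both") {
  .item(item, module, prompt, .onset_year_min, .onset_year_max,
        extra = as.character(mhq_onset_unknown()),
        parents = parents, ask = ask, waves = waves)
}

.build_default_items <- function() {
  rows <- list(
    # -- screening: self-reported clinician diagnoses ----------------------
    .item("srdx_none", "screening", "No diagnosis from the checklist", 0, 1),
    .item("srdx_depression", "screening", "Clinician diagnosis: depression", 0, 1),
    .item("srdx_bipolar", "screening", "Clinician diagnosis: mania/bipolar", 0, 1),
    .item("srdx_anxiety", "screening", "Clinician diagnosis: anxiety/GAD", 0, 1),
    .item("srdx_eating", "screening", "Clinician diagnosis: eating disorder", 0, 1),
    .item("srdx_other", "screening", "Clinician diagnosis: other condition", 0, 1),
    .item("srdx_panic_attacks", "screening", "Clinician diagnosis: panic attacks",
          0, 1, waves = "mhq2"),
    .item("srdx_panic_disorder", "screening", "Clinician diagnosis: panic disorder",
          0, 1, waves = "mhq2"),
    .item("srdx_panic_combined", "screening",
          "Clinician diagnosis: panic attacks or panic disorder", 0, 1,
          waves = "mhq1"),

    # -- current depression: PHQ-9 (0 not at all .. 3 nearly every day) ----
    .item(paste0("phq9_", 1:9), "depression_current",
          paste0("PHQ-9 item ", 1:9), 0, 3),

    # -- lifetime depression: CIDI-SF style ---------------------------------
    .item("dep_screen_low", "depression_lifetime",
          "Ever 2+ weeks feeling sad/depressed most of the day", 0, 1),
    .item("dep_screen_anh", "depression_lifetime",
          "Ever 2+ weeks losing interest in most things", 0, 1),
    .item(paste0("dep_sym_", c("tired", "appetite", "sleep", "concentration",
                               "worthless", "death")),
          "depression_lifetime",
          paste0("Worst-episode symptom: ",
                 c("tiredness", "appetite/weight change", "sleep problems",
                   "trouble concentrating", "worthlessness",
                   "thoughts of death")),
          0, 1, parents = "dep_screen_low,dep_screen_anh", ask = "1;1"),
    .item("dep_impair", "depression_lifetime",
          "Interference with life (0 not at all..3 a lot)", 0, 3,
          parents = "dep_screen_low,dep_screen_anh", ask = "1;1"),
    .onset_item("dep_onset_year", "depression_lifetime",
                "Year the worst episode began",
                parents = "dep_screen_low,dep_screen_anh", ask = "1;1"),
    # melancholic / atypical specifier probes (second wave only)
    .item(c("dep_mel_nonreactive", "dep_mel_earlywake", "dep_mel_worsemorning",
            "dep_mel_psychomotor", "dep_mel_guilt"),
          "depression_lifetime",
          paste0("Specifier: ", c("mood unreactive to good events",
                                  "early-morning waking", "worse in the morning",
                                  "marked psychomotor change", "excessive guilt")),
          0, 1, parents = "dep_screen_low,dep_screen_anh", ask = "1;1",
          waves = "mhq2"),
    .item(c("dep_aty_reactive", "dep_aty_weightgain", "dep_aty_hypersomnia",
            "dep_aty_leaden", "dep_aty_rejection"),
          "depression_lifetime",
          paste0("Specifier: ", c("mood brightens with good events",
                                  "weight gain", "hypersomnia",
                                  "leaden heaviness", "rejection sensitivity")),
          0, 1, parents = "dep_screen_low,dep_screen_anh", ask = "1;1",
          waves = "mhq2"),
    # treatment response (second wave only)
    .item("dep_med_ever", "depression_lifetime", "Ever took antidepressants",
          0, 1, parents = "dep_screen_low,dep_screen_anh", ask = "1;1",
          waves = "mhq2"),
    .item("dep_med_helped", "depression_lifetime", "Antidepressants helped",
          0, 1, parents = "dep_med_ever", ask = "1", waves = "mhq2"),
    .item("dep_ther_ever", "depression_lifetime", "Ever had talking therapy",
          0, 1, parents = "dep_screen_low,dep_screen_anh", ask = "1;1",
          waves = "mhq2"),
    .item("dep_ther_helped", "depression_lifetime", "Talking therapy helped",
          0, 1, parents = "dep_ther_ever", ask = "1", waves = "mhq2"),

    # -- mood change: lifetime manic symptoms -------------------------------
    .item("man_elation", "mania", "Ever a period of extreme elation", 0, 1),
    .item("man_irrit", "mania", "Ever a period of extreme irritability", 0, 1),
    .item(paste0("man_sym_", c("active", "talk", "racing", "sleep",
                               "distract", "confid", "risky")),
          "mania",
          paste0("Manic symptom: ", c("more active", "more talkative",
                                      "racing thoughts", "less need for sleep",
                                      "easily distracted", "more confident",
                                      "risky behaviour")),
          0, 1, parents = "man_elation,man_irrit", ask = "1;1"),
    .item("man_duration", "mania",
          "Longest episode (0 <1 day, 1 1 day to <1 week, 2 a week or more)",
          0, 2, parents = "man_elation,man_irrit", ask = "1;1"),
    .onset_item("man_onset_year", "mania", "Year symptoms first occurred",
                parents = "man_elation,man_irrit", ask = "1;1"),

    # -- current anxiety: GAD-7 ---------------------------------------------
    .item(paste0("gad7_", 1:7), "anxiety_current",
          paste0("GAD-7 item ", 1:7), 0, 3),

    # -- lifetime panic: CIDI-SF style (second wave only) -------------------
    .item("pan_gate", "panic",
          "Ever a sudden attack of intense fear or discomfort", 0, 1,
          waves = "mhq2"),
    .item(paste0("pan_sym_", 1:13), "panic",
          paste0("Panic attack symptom ", 1:13), 0, 1,
          parents = "pan_gate", ask = "1", waves = "mhq2"),
    .item("pan_recurrent", "panic", "More than one attack", 0, 1,
          parents = "pan_gate", ask = "1", waves = "mhq2"),
    .item("pan_unexpected", "panic", "Some attacks out of the blue", 0, 1,
          parents = "pan_gate", ask = "1", waves = "mhq2"),
    .item("pan_worry_month", "panic",
          "A month or more of worry about attacks or behaviour change", 0, 1,
          parents = "pan_gate", ask = "1", waves = "mhq2"),
    .onset_item("pan_onset_year", "panic", "Year of first attack",
                parents = "pan_gate", ask = "1", waves = "mhq2"),

    # -- adverse events -----------------------------------------------------
    .item(paste0("cts_", 1:4), "childhood_adversity",
          paste0("Childhood trauma item ", 1:4,
                 " (0 never..4 very often)"), 0, 4),
    .item("cts_loved", "childhood_adversity",
          "Felt loved as a child (0 never..4 very often; reverse keyed)", 0, 4),
    .item("adv_adult_ever", "adult_adversity",
          "Any adverse/abusive event in adult life", 0, 1, waves = "mhq2"),

    # -- alcohol: AUDIT -----------------------------------------------------
    .item(paste0("audit_", 1:8), "alcohol",
          paste0("AUDIT item ", 1:8, " (0..4)"), 0, 4),
    .item(c("audit_9", "audit_10"), "alcohol",
          paste0("AUDIT item ", 9:10, " (0, 2 or 4)"), 0, 4, extra = "skip13"),

    # -- cannabis -----------------------------------------------------------
    .item("can_freq", "cannabis",
          "Cannabis use (0 never, 1 a few times, 2 monthly, 3 weekly, 4 every day)",
          0, 4),
    .onset_item("can_onset_year", "cannabis", "Year of first cannabis use",
                parents = "can_freq", ask = "1,2,3,4"),

    # -- harm behaviours ----------------------------------------------------
    .item("sh_ever", "self_harm", "Ever deliberately harmed self", 0, 1),
    .item("sh_intent", "self_harm", "Ever self-harmed intending to end life",
          0, 1, parents = "sh_ever", ask = "1"),
    .onset_item("sh_onset_year", "self_harm", "Year of first self-harm",
                parents = "sh_ever", ask = "1"),

    # -- eating patterns (second wave only) ---------------------------------
    .item("ed_lowest_weight_kg", "eating",
          "Lowest adult weight in kg", 25, 200, waves = "mhq2"),
    .item("ed_fear", "eating", "Intense fear of gaining weight at low weight",
          0, 1, waves = "mhq2"),
    .item("ed_prevent", "eating",
          "Persistent behaviour to prevent weight gain", 0, 1, waves = "mhq2"),
    .item("ed_bodyimage", "eating",
          "Felt fat / body-image disturbance at low weight", 0, 1,
          waves = "mhq2"),
    .item("ed_binge", "eating",
          "Recurrent binges: large amounts with loss of control", 0, 1,
          waves = "mhq2"),
    .item("ed_binge_weekly_3m", "eating",
          "Binges at least weekly for 3+ months", 0, 1,
          parents = "ed_binge", ask = "1", waves = "mhq2"),
    .item("ed_distress", "eating", "Marked distress about binges", 0, 1,
          parents = "ed_binge", ask = "1", waves = "mhq2"),
    .item("ed_binge_anorexia_only", "eating",
          "Binges only during the low-weight period", 0, 1,
          parents = "ed_binge", ask = "1", waves = "mhq2"),
    .item("ed_comp", "eating",
          "Compensatory behaviour to avoid weight gain after eating", 0, 1,
          waves = "mhq2"),
    .item("ed_comp_weekly_3m", "eating",
          "Compensation at least weekly for 3+ months", 0, 1,
          parents = "ed_comp", ask = "1", waves = "mhq2"),
    .item("ed_comp_purging", "eating",
          "Compensation by vomiting or laxatives (purging)", 0, 1,
          parents = "ed_comp", ask = "1", waves = "mhq2"),

    # -- social situation ---------------------------------------------------
    .item("soc_lives_alone", "social", "Lives alone", 0, 1),
    .item("soc_visits_lt_monthly", "social",
          "Visits from friends/family less than monthly", 0, 1),
    .item("soc_no_weekly_activity", "social",
          "No weekly group activity", 0, 1),
    .item(paste0("lone_", 1:3), "loneliness",
          paste0("UCLA-3 loneliness item ", 1:3, " (1 hardly ever..3 often)"),
          1, 3, waves = "mhq2"),

    # -- wellbeing ----------------------------------------------------------
    .item(paste0("brs_", 1:6), "resilience",
          paste0("Brief Resilience Scale item ", 1:6,
                 ifelse(1:6 %in% c(2, 4, 6), " (reverse keyed)", "")),
          1, 5, waves = "mhq2"),
    .item("vas", "general_health",
          "EQ-5D visual analogue scale, 0 worst to 100 best health", 0, 100)
  )
  do.call(rbind, rows)
}

#' Default questionnaire data dictionary
#'
#' Builds the packaged item codebook for a two-wave mental-health
#' questionnaire: item codes, module membership, integer value domains,
#' missing-value sentinels and skip (routing) rules. The second wave extends
#' the first with panic, eating-disorder, depression-specifier, treatment
#' response, loneliness, resilience and adult-adversity items, and splits the
#' combined "panic attacks or panic disorder" diagnosis checkbox in two.
#'
#' Skip rules use OR semantics over one or more parent items: a child item is
#' asked when *any* listed parent takes one of its asking values, and is
#' skipped (code [mhq_skipped()]) when all parents are answered and none
#' does.
#'
#' @param sentinels Integer codes treated as missing answers
#'   (default `-818` "prefer not to answer", `-121` "do not know").
#' @return A `mhq_dictionary` object: a tibble with one row per item plus a
#'   `sentinels` attribute.
#' @export
mhq_dictionary <- function(sentinels = c(-818L, -121L)) {
  items <- .build_default_items()
  new_dictionary(items, sentinels = sentinels)
}

#' Construct and validate a data dictionary
#'
#' @param items Data frame with columns `item`, `module`, `prompt`, `min`,
#'   `max`, `extra` (extra allowed codes, comma-separated, or "skip13" for
#'   the AUDIT 0/2/4 domain), `parents` (comma-separated parent item codes,
#'   "" for none), `ask` (per-parent asking values, `;`-separated across
#'   parents, `,`-separated within), `waves` ("both", "mhq1" or "mhq2").
#' @param sentinels Integer missing-value codes.
#' @return A validated `mhq_dictionary`.
#' @export
new_dictionary <- function(items, sentinels = c(-818L, -121L)) {
  d <- tibble::as_tibble(items)
  attr(d, "sentinels") <- as.integer(sentinels)
  class(d) <- c("mhq_dictionary", class(d))
  validate_dictionary(d)
  d
}

#' @export
print.mhq_dictionary <- function(x, ...) {
  cat(sprintf(
    "<mhq_dictionary> %d items, %d modules, sentinels: %s\n",
    nrow(x), length(unique(x$module)),
    paste(dictionary_sentinels(x), collapse = ", ")
  ))
  mods <- table(x$module)
  cat(paste(sprintf("  %-22s %3d items", names(mods), as.integer(mods)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Missing-value sentinel codes of a dictionary
#' @param dict A `mhq_dictionary`.
#' @return Integer vector.
#' @export
dictionary_sentinels <- function(dict) {
  attr(dict, "sentinels")
}

# parse "a,b" / "1;1" into list(parent = values)
.skip_rule <- function(row) {
  if (is.na(row$parents) || row$parents == "") {
    return(NULL)
  }
  parents <- strsplit(row$parents, ",", fixed = TRUE)[[1]]
  asks <- strsplit(row$ask, ";", fixed = TRUE)[[1]]
  if (length(asks) == 1L && length(parents) > 1L) {
    asks <- rep(asks, length(parents))
  }
  stats::setNames(
    lapply(asks, function(a) as.integer(strsplit(a, ",", fixed = TRUE)[[1]])),
    parents
  )
}

# allowed codes for one item (excluding sentinels / skipped)
.item_domain <- function(row) {
  if (identical(row$extra, "skip13")) {
    return(c(0L, 2L, 4L))
  }
  dom <- seq.int(row$min, row$max)
  if (!is.na(row$extra) && nzchar(row$extra)) {
    dom <- c(dom, as.integer(strsplit(row$extra, ",", fixed = TRUE)[[1]]))
  }
  dom
}

#' Validate a data dictionary
#'
#' Checks item-code uniqueness, that every skip rule references an existing
#' item, that the skip graph is acyclic, and that no value domain overlaps
#' the missing sentinels or the internal skipped code.
#'
#' @param dict A `mhq_dictionary`.
#' @return The dictionary, invisibly, or an error.
#' @export
validate_dictionary <- function(dict) {
  dup <- dict$item[duplicated(dict$item)]
  if (length(dup) > 0) {
    stop("duplicate item_code ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sent <- dictionary_sentinels(dict)
  # skip edges child -> parents
  edges <- list()
  for (i in seq_len(nrow(dict))) {
    row <- dict[i, ]
    rule <- .skip_rule(row)
    if (!is.null(rule)) {
      missing_parent <- setdiff(names(rule), dict$item)
      if (length(missing_parent) > 0) {
        stop("skip rule of '", row$item, "' references unknown item ",
             paste(missing_parent, collapse = ", "), call. = FALSE)
      }
      edges[[row$item]] <- names(rule)
    }
    dom <- .item_domain(row)
    bad <- intersect(dom, c(sent, mhq_skipped()))
    if (length(bad) > 0) {
      stop("value domain of '", row$item,
           "' overlaps sentinel/skip codes: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  # cycle detection by iterative removal of resolved nodes
  unresolved <- names(edges)
  repeat {
    free <- unresolved[vapply(unresolved, function(it) {
      !any(edges[[it]] %in% unresolved)
    }, logical(1))]
    if (length(free) == 0) break
    unresolved <- setdiff(unresolved, free)
  }
  if (length(unresolved) > 0) {
    stop("cyclic skip rule involving: ", paste(unresolved, collapse = ", "),
         call. = FALSE)
  }
  invisible(dict)
}

#' Items administered in a given wave
#'
#' @param dict A `mhq_dictionary`.
#' @param wave `"MHQ1"` or `"MHQ2"`.
#' @return Character vector of item codes.
#' @export
wave_items <- function(dict, wave = c("MHQ2", "MHQ1")) {
  wave <- match.arg(wave)
  keep <- dict$waves == "both" | dict$waves == tolower(wave)
  dict$item[keep]
}

#' Read a data dictionary from YAML or JSON
#'
#' The file holds a `sentinels` vector and an `items` list, one entry per
#' item with the fields of [new_dictionary()]. The packaged default
#' dictionary is shipped at
#' `system.file("extdata", "mhq_dictionary.yaml", package = "mhqtools")`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A validated `mhq_dictionary`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) {
    stop("dictionary file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  items <- do.call(rbind, lapply(raw$items, function(e) {
    data.frame(
      item = e$item, module = e$module, prompt = e$prompt,
      min = as.integer(e$min), max = as.integer(e$max),
      extra = if (is.null(e$extra)) "" else as.character(e$extra),
      parents = if (is.null(e$parents)) "" else as.character(e$parents),
      ask = if (is.null(e$ask)) "" else as.character(e$ask),
      waves = if (is.null(e$waves)) "both" else e$waves,
      stringsAsFactors = FALSE
    )
  }))
  new_dictionary(items, sentinels = as.integer(raw$sentinels))
}

#' Write a data dictionary to YAML
#'
#' @param dict A `mhq_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  items <- lapply(seq_len(nrow(dict)), function(i) {
    row <- as.list(dict[i, , drop = FALSE])
    row <- lapply(row, function(v) v[[1]])
    row[vapply(row, function(v) !is.na(v) && nzchar(as.character(v)) ||
                 is.numeric(v), logical(1))]
  })
  yaml::write_yaml(
    list(sentinels = as.integer(dictionary_sentinels(dict)), items = items),
    path
  )
  invisible(path)
}
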