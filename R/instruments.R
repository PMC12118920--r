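#' Instrument scoring thresholds
#'
#' Central block of tunable scoring cut-points. The derived-variable names
#' are fixed by the questionnaire's codebook, but several numeric thresholds
#' are conventions rather than published constants, so they are exposed here.
#'
#' @param gad7_cut GAD-7 caseness threshold on the 0-21 total (default 10).
#' @param audit_harmful_cut AUDIT harmful-drinking threshold on the 0-40
#'   total (default 16).
#' @param brs_low_cut Brief Resilience Scale "low resilience" upper bound:
#'   low is a mean strictly below this (default 3, i.e. 1 to 2.99).
#' @param cts_abuse_cut CTS-5 abuse/neglect domain positive when the item
#'   frequency is at least this (default 2 = "sometimes").
#' @param cts_loved_cut Reverse-keyed "felt loved" domain positive when the
#'   item is at most this (default 1 = "rarely").
#' @return Named list.
#' @export
instrument_thresholds <- function(gad7_cut = 10L, audit_harmful_cut = 16L,
                                  brs_low_cut = 3, cts_abuse_cut = 2L,
                                  cts_loved_cut = 1L) {
  list(gad7_cut = gad7_cut, audit_harmful_cut = audit_harmful_cut,
       brs_low_cut = brs_low_cut, cts_abuse_cut = cts_abuse_cut,
       cts_loved_cut = cts_loved_cut)
}

.as_item_matrix <- function(items, k, what) {
  m <- as.matrix(items)
  if (is.vector(items)) m <- matrix(items, nrow = 1)
  if (ncol(m) != k) {
    stop(what, " expects ", k, " items, got ", ncol(m), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

.check_domain <- function(m, allowed, what) {
  bad <- !is.na(m) & !(m %in% allowed)
  if (any(bad)) {
    stop("out-of-domain value for ", what, ": ", m[which(bad)[1]],
         call. = FALSE)
  }
}

.score_frame <- function(total, caseness, n_missing) {
  status <- ifelse(n_missing > 0L, "missing", "scored")
  total <- as.integer(total)
  total[status == "missing"] <- NA_integer_
  caseness[status == "missing"] <- NA
  tibble::tibble(total = total, caseness = caseness,
                 n_missing = as.integer(n_missing), status = status)
}

#' Score the PHQ-9 (current depression)
#'
#' Total is the sum of the nine 0-3 items (range 0-27). Caseness follows the
#' diagnostic-algorithm convention: at least five items scored 2 or more
#' ("more than half the days"), where item 9 (self-harm thoughts) counts
#' from 1 ("several days"), and at least one of the two core items (1
#' depressed mood, 2 anhedonia) is among those scored 2 or more. Any missing
#' item makes the score missing (complete-case; no prorating).
#'
#' @param items n x 9 matrix/data frame (or length-9 vector) coded 0-3.
#' @return Tibble with `total`, `caseness`, `n_missing`, `status`.
#' @export
score_phq9 <- function(items) {
  m <- .as_item_matrix(items, 9, "PHQ-9")
  .check_domain(m, 0:3, "PHQ-9")
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m)
  qualifying <- rowSums(m[, 1:8, drop = FALSE] >= 2L) + (m[, 9] >= 1L)
  core <- m[, 1] >= 2L | m[, 2] >= 2L
  caseness <- qualifying >= 5L & core
  .score_frame(total, caseness, n_missing)
}

#' Score the GAD-7 (current anxiety)
#'
#' Total 0-21; caseness is total at or above the threshold (default 10).
#'
#' @param items n x 7 matrix/data frame coded 0-3.
#' @param cut Caseness threshold.
#' @return Tibble as in [score_phq9()].
#' @export
score_gad7 <- function(items, cut = instrument_thresholds()$gad7_cut) {
  m <- .as_item_matrix(items, 7, "GAD-7")
  .check_domain(m, 0:3, "GAD-7")
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m)
  .score_frame(total, total >= cut, n_missing)
}

#' Score the AUDIT (12-month alcohol use)
#'
#' Items 1-8 are coded 0-4; items 9-10 take 0, 2 or 4. Total 0-40; harmful
#' drinking is total at or above the threshold (default 16).
#'
#' @param items n x 10 matrix/data frame.
#' @param cut Harmful-drinking threshold.
#' @return Tibble as in [score_phq9()].
#' @export
score_audit <- function(items, cut = instrument_thresholds()$audit_harmful_cut) {
  m <- .as_item_matrix(items, 10, "AUDIT")
  .check_domain(m[, 1:8, drop = FALSE], 0:4, "AUDIT items 1-8")
  .check_domain(m[, 9:10, drop = FALSE], c(0L, 2L, 4L), "AUDIT items 9-10")
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m)
  .score_frame(total, total >= cut, n_missing)
}

#' Score the 5-item Childhood Trauma Screener
#'
#' Four abuse/neglect items coded 0 "never" to 4 "very often" and one
#' reverse-keyed "felt loved" item. A domain is positive when its answer
#' crosses the per-item threshold (abuse at or above `cts_abuse_cut`;
#' "felt loved" at or below `cts_loved_cut`). Any-adversity is the OR over
#' scored domains: missing domains are excluded, but if all five are missing
#' the result is missing.
#'
#' @param items n x 5 matrix/data frame: four abuse items then "felt loved".
#' @param thresholds From [instrument_thresholds()].
#' @return Tibble with `any_adversity`, per-domain flags `domain_1..4`,
#'   `domain_loved`, `n_missing`, `status`.
#' @export
score_cts5 <- function(items, thresholds = instrument_thresholds()) {
  m <- .as_item_matrix(items, 5, "CTS-5")
  .check_domain(m, 0:4, "CTS-5")
  flags <- cbind(
    m[, 1:4, drop = FALSE] >= thresholds$cts_abuse_cut,
    m[, 5] <= thresholds$cts_loved_cut
  )
  n_missing <- rowSums(is.na(m))
  any_true <- rowSums(flags, na.rm = TRUE) > 0
  all_missing <- n_missing == 5L
  any_adversity <- ifelse(any_true, TRUE, ifelse(all_missing, NA, FALSE))
  out <- tibble::tibble(
    any_adversity = any_adversity,
    domain_1 = flags[, 1], domain_2 = flags[, 2], domain_3 = flags[, 3],
    domain_4 = flags[, 4], domain_loved = flags[, 5],
    n_missing = n_missing,
    status = ifelse(all_missing, "missing", "scored")
  )
  out
}

#' Score the 3-item UCLA loneliness scale
#'
#' Items coded 1-3; total 3 (least lonely) to 9 (most lonely).
#'
#' @param items n x 3 matrix/data frame coded 1-3.
#' @return Tibble with `total`, `n_missing`, `status` (no caseness).
#' @export
score_loneliness <- function(items) {
  m <- .as_item_matrix(items, 3, "loneliness")
  .check_domain(m, 1:3, "loneliness")
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m)
  out <- .score_frame(total, rep(NA, nrow(m)), n_missing)
  out$caseness <- NULL
  out
}

#' Score the Brief Resilience Scale
#'
#' Six items coded 1-5; items 2, 4 and 6 are reverse-keyed (6 minus the
#' answer) before taking the mean. Low resilience is a mean strictly below
#' the cut (default 3, i.e. 1 to 2.99 on the 1-5 scale).
#'
#' @param items n x 6 matrix/data frame coded 1-5.
#' @param cut Low-resilience bound.
#' @return Tibble with `mean`, `low_resilience`, `n_missing`, `status`.
#' @export
score_brs <- function(items, cut = instrument_thresholds()$brs_low_cut) {
  m <- .as_item_matrix(items, 6, "BRS")
  .check_domain(m, 1:5, "BRS")
  rev_idx <- c(2L, 4L, 6L)
  m[, rev_idx] <- 6L - m[, rev_idx]
  n_missing <- rowSums(is.na(m))
  mn <- rowMeans(m)
  status <- ifelse(n_missing > 0L, "missing", "scored")
  mn[status == "missing"] <- NA
  tibble::tibble(mean = mn, low_resilience = mn < cut,
                 n_missing = n_missing, status = status)
}

.items_or_na <- function(d, cols) {
  present <- intersect(cols, names(d))
  m <- matrix(NA_integer_, nrow = nrow(d), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (col in present) m[, col] <- d[[col]]
  m
}

#' Score all instruments for a response table
#'
#' One row per participant with every scale total and caseness flag. Items
#' not administered in the table's wave yield missing scores.
#'
#' @param x An `mhq_responses` object.
#' @param thresholds From [instrument_thresholds()].
#' @return Tibble keyed by `pid` with columns `phq9_total`, `phq9_case`,
#'   `gad7_total`, `gad7_case`, `audit_total`, `audit_harmful`, `cts_any`,
#'   `lone_total`, `brs_mean`, `brs_low`, `vas`.
#' @export
score_instruments <- function(x, thresholds = instrument_thresholds()) {
  d <- response_data(x)
  phq <- score_phq9(.items_or_na(d, paste0("phq9_", 1:9)))
  gad <- score_gad7(.items_or_na(d, paste0("gad7_", 1:7)),
                    cut = thresholds$gad7_cut)
  aud <- score_audit(.items_or_na(d, paste0("audit_", 1:10)),
                     cut = thresholds$audit_harmful_cut)
  cts <- score_cts5(.items_or_na(d, c(paste0("cts_", 1:4), "cts_loved")),
                    thresholds = thresholds)
  lon <- score_loneliness(.items_or_na(d, paste0("lone_", 1:3)))
  brs <- score_brs(.items_or_na(d, paste0("brs_", 1:6)),
                   cut = thresholds$brs_low_cut)
  vas <- if ("vas" %in% names(d)) d$vas else rep(NA_integer_, nrow(d))
  tibble::tibble(
    pid = d$pid,
    phq9_total = phq$total, phq9_case = phq$caseness,
    gad7_total = gad$total, gad7_case = gad$caseness,
    audit_total = aud$total, audit_harmful = aud$caseness,
    cts_any = cts$any_adversity,
    lone_total = lon$total,
    brs_mean = brs$mean, brs_low = brs$low_resilience,
    vas = as.integer(vas)
  )
}
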