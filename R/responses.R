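#' Construct a response table
#'
#' A response table holds one wave of participant-by-item coded answers as a
#' wide tibble: a `pid` column plus one integer column per item. Missing
#' answers are `NA`; items routed past by skip logic carry [mhq_skipped()].
#'
#' @param data Tibble/data frame with `pid` plus item columns (integer).
#' @param dict The `mhq_dictionary` the items belong to.
#' @param wave `"MHQ1"` or `"MHQ2"`.
#' @param completed Optional logical vector (one per participant): completed
#'   all mental-health modules. If `NULL`, computed as "every applicable item
#'   answered or skipped".
#' @param validate Run [validate_responses()] (default `TRUE`).
#' @return An `mhq_responses` object.
#' @export
new_responses <- function(data, dict, wave = c("MHQ2", "MHQ1"),
                          completed = NULL, validate = TRUE) {
  wave <- match.arg(wave)
  data <- tibble::as_tibble(data)
  if (!"pid" %in% names(data)) {
    stop("response table needs a 'pid' column", call. = FALSE)
  }
  if (anyDuplicated(data$pid)) {
    stop("duplicated participant id within one wave: ",
         paste(utils::head(unique(data$pid[duplicated(data$pid)]), 3),
               collapse = ", "), call. = FALSE)
  }
  data$pid <- as.character(data$pid)
  item_cols <- setdiff(names(data), c("pid", "completed"))
  unknown <- setdiff(item_cols, dict$item)
  if (length(unknown) > 0) {
    stop("items not in dictionary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (col in item_cols) data[[col]] <- as.integer(data[[col]])
  if (is.null(completed)) {
    completed <- if ("completed" %in% names(data)) {
      as.logical(data$completed)
    } else {
      .compute_completion(data, dict)
    }
  }
  data$completed <- NULL
  obj <- structure(
    list(data = data, dict = dict, wave = wave,
         completed = as.logical(completed)),
    class = "mhq_responses"
  )
  if (validate) validate_responses(obj)
  obj
}

#' @export
print.mhq_responses <- function(x, ...) {
  cat(sprintf(
    "<mhq_responses> wave %s: %d participants x %d items (%d completed all modules)\n",
    x$wave, nrow(x$data), ncol(x$data) - 1L, sum(x$completed, na.rm = TRUE)
  ))
  invisible(x)
}

#' Participant ids of a response table
#' @param x An `mhq_responses` object.
#' @return Character vector.
#' @export
participants <- function(x) x$data$pid

#' Item data of a response table
#' @param x An `mhq_responses` object.
#' @param completed_only Drop participants who did not complete all modules
#'   (default `FALSE`).
#' @return Tibble with `pid` and item columns.
#' @export
response_data <- function(x, completed_only = FALSE) {
  if (completed_only) x$data[x$completed, , drop = FALSE] else x$data
}

# an item is "applicable" when not skipped; completion = all applicable
# items of the wave answered (sentinel answers count as answered upstream:
# they arrive here as values or have already been normalised to NA by the
# loader, which computes completion before normalisation)
.compute_completion <- function(data, dict) {
  item_cols <- setdiff(names(data), c("pid", "completed"))
  miss <- vapply(item_cols, function(col) is.na(data[[col]]), logical(nrow(data)))
  if (nrow(data) == 1L) miss <- matrix(miss, nrow = 1L)
  rowSums(miss) == 0L
}

#' Validate a response table
#'
#' Checks that coded values lie in each item's value domain and that the
#' skipped code appears only where the item's skip rule fires (all parents
#' answered, none endorsing). Blank children of unanswered parents are
#' missing, not skipped.
#'
#' @param x An `mhq_responses` object.
#' @return `x` invisibly, or an error naming participant and item.
#' @export
validate_responses <- function(x) {
  d <- x$data
  dict <- x$dict
  for (col in setdiff(names(d), "pid")) {
    row <- dict[dict$item == col, ]
    dom <- .item_domain(row)
    v <- d[[col]]
    bad <- !is.na(v) & v != mhq_skipped() & !(v %in% dom)
    if (any(bad)) {
      stop("out-of-domain value for item '", col, "', participant ",
           d$pid[which(bad)[1]], ": ", v[which(bad)[1]], call. = FALSE)
    }
    rule <- .skip_rule(row)
    sk <- !is.na(v) & v == mhq_skipped()
    if (is.null(rule)) {
      if (any(sk)) {
        stop("item '", col, "' has no skip rule but is coded skipped for ",
             "participant ", d$pid[which(sk)[1]], call. = FALSE)
      }
    } else if (any(sk)) {
      fires <- .skip_fires(d, rule)
      bad <- sk & !fires
      if (any(bad)) {
        stop("skipped value without firing skip rule: item '", col,
             "', participant ", d$pid[which(bad)[1]], call. = FALSE)
      }
    }
  }
  invisible(x)
}

# TRUE where the skip rule fires: all parents answered (value or skipped),
# none taking an asking value
.skip_fires <- function(d, rule) {
  fires <- rep(TRUE, nrow(d))
  endorsed <- rep(FALSE, nrow(d))
  for (p in names(rule)) {
    pv <- d[[p]]
    if (is.null(pv)) pv <- rep(NA_integer_, nrow(d))
    fires <- fires & !is.na(pv)
    endorsed <- endorsed | (!is.na(pv) & pv %in% rule[[p]])
  }
  fires & !endorsed
}

#' Apply skip logic to raw item values
#'
#' Overwrites child items with the skipped code wherever their skip rule
#' fires, walking items in dependency order so that children of skipped
#' parents are themselves skipped. Used by the loader (to classify blank
#' cells) and by the synthetic generator.
#'
#' @param data Wide tibble of raw item values (`pid` plus items).
#' @param dict The dictionary.
#' @return The tibble with skipped codes in place.
#' @export
apply_skip_logic <- function(data, dict) {
  item_cols <- setdiff(names(data), c("pid", "completed"))
  ordered <- .topo_items(dict)
  for (col in intersect(ordered, item_cols)) {
    rule <- .skip_rule(dict[dict$item == col, ])
    if (is.null(rule)) next
    if (!all(names(rule) %in% names(data))) next
    fires <- .skip_fires(data, rule)
    data[[col]][fires] <- mhq_skipped()
  }
  data
}

# items sorted so parents precede children
.topo_items <- function(dict) {
  remaining <- dict$item
  parents_of <- lapply(seq_len(nrow(dict)), function(i) {
    r <- .skip_rule(dict[i, ])
    if (is.null(r)) character(0) else names(r)
  })
  names(parents_of) <- dict$item
  out <- character(0)
  while (length(remaining) > 0) {
    free <- remaining[vapply(remaining, function(it) {
      !any(parents_of[[it]] %in% remaining)
    }, logical(1))]
    out <- c(out, free)
    remaining <- setdiff(remaining, free)
  }
  out
}

#' Read a wave of item responses from CSV/TSV
#'
#' Expects a header row with a `pid` column and one column per item. Blank
#' cells and the literal `NA` are unanswered; dictionary sentinel codes
#' (e.g. "prefer not to answer") are normalised to missing. Blank cells
#' whose skip rule fires are classified as skipped rather than missing.
#' Unknown columns are dropped with a warning. Values outside an item's
#' domain raise an error naming the participant and item.
#'
#' The completion flag (answered all applicable items) is computed before
#' sentinel normalisation, so "prefer not to answer" counts as an answer.
#' A `completed` column in the file, if present, takes precedence.
#'
#' @param path CSV (or TSV with `sep = "\t"`) file path.
#' @param dict An `mhq_dictionary`.
#' @param wave `"MHQ1"` or `"MHQ2"`.
#' @param sep Field separator, default comma.
#' @return An `mhq_responses` object.
#' @export
load_responses <- function(path, dict, wave = c("MHQ2", "MHQ1"), sep = ",") {
  wave <- match.arg(wave)
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!"pid" %in% names(raw)) {
    stop("response file has no 'pid' column", call. = FALSE)
  }
  unknown <- setdiff(names(raw), c("pid", "completed", dict$item))
  if (length(unknown) > 0) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  item_cols <- setdiff(names(raw), c("pid", "completed"))
  out <- tibble::tibble(pid = as.character(raw$pid))
  for (col in item_cols) out[[col]] <- suppressWarnings(as.integer(raw[[col]]))
  # classify blanks: skipped where the rule fires, else missing
  out <- apply_skip_logic_blanks(out, dict)
  file_completed <- if ("completed" %in% names(raw)) {
    as.logical(as.integer(raw$completed))
  } else {
    NULL
  }
  # completion judged before sentinel normalisation
  completed <- if (is.null(file_completed)) {
    .compute_completion(out, dict)
  } else {
    file_completed
  }
  sent <- dictionary_sentinels(dict)
  for (col in item_cols) {
    v <- out[[col]]
    out[[col]][!is.na(v) & v %in% sent] <- NA_integer_
  }
  new_responses(out, dict, wave = wave, completed = completed)
}

# only blank (NA) cells may become skipped on load; answered cells are kept
apply_skip_logic_blanks <- function(data, dict) {
  ordered <- .topo_items(dict)
  item_cols <- setdiff(names(data), c("pid", "completed"))
  for (col in intersect(ordered, item_cols)) {
    rule <- .skip_rule(dict[dict$item == col, ])
    if (is.null(rule) || !all(names(rule) %in% names(data))) next
    fires <- .skip_fires(data, rule)
    blank <- is.na(data[[col]])
    data[[col]][blank & fires] <- mhq_skipped()
  }
  data
}

#' Write a normalised response table to CSV
#'
#' Skipped cells are written blank (they are re-derivable from the skip
#' rules); missing cells are written as `NA`; the completion flag is written
#' as a 0/1 `completed` column so that a round trip preserves it.
#'
#' @param x An `mhq_responses` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  d <- x$data
  out <- data.frame(pid = d$pid, stringsAsFactors = FALSE)
  for (col in setdiff(names(d), "pid")) {
    v <- d[[col]]
    ch <- ifelse(is.na(v), "NA", ifelse(v == mhq_skipped(), "", as.character(v)))
    out[[col]] <- ch
  }
  out$completed <- as.integer(x$completed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge the two questionnaire waves on participant id
#'
#' Partitions participants into those with both waves, first wave only and
#' second wave only, and reports the partition sizes.
#'
#' @param t1 `mhq_responses` for the first wave.
#' @param t2 `mhq_responses` for the second wave.
#' @return An `mhq_cohort`: list with the two tables, id sets `both`,
#'   `mhq1_only`, `mhq2_only`, and a `counts` vector.
#' @export
merge_waves <- function(t1, t2) {
  ids1 <- participants(t1)
  ids2 <- participants(t2)
  both <- intersect(ids1, ids2)
  res <- structure(
    list(
      mhq1 = t1, mhq2 = t2,
      both = both,
      mhq1_only = setdiff(ids1, ids2),
      mhq2_only = setdiff(ids2, ids1)
    ),
    class = "mhq_cohort"
  )
  res$counts <- c(
    both = length(res$both),
    mhq1_only = length(res$mhq1_only),
    mhq2_only = length(res$mhq2_only)
  )
  res
}

#' @export
print.mhq_cohort <- function(x, ...) {
  cat(sprintf(
    "<mhq_cohort> both waves: %d, first only: %d, second only: %d\n",
    x$counts["both"], x$counts["mhq1_only"], x$counts["mhq2_only"]
  ))
  invisible(x)
}
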