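# Independent brute-force oracles: scalar, loop-based re-evaluations of the
# scoring and phenotype rules, written directly from their definitions and
# deliberately structured differently from the package implementation
# (explicit if/else per participant, no shared helpers).

SKIP <- mhq_skipped()

# scalar value with skip treated as "criterion not met" (0); NA preserved
.o_val <- function(v) {
  if (is.na(v)) NA_integer_ else if (v == SKIP) 0L else v
}

oracle_sum <- function(items) {
  s <- 0L
  for (v in items) {
    if (is.na(v)) return(NA_integer_)
    s <- s + v
  }
  s
}

oracle_phq9_case <- function(items) {
  if (any(is.na(items))) return(NA)
  cnt <- 0L
  for (j in 1:8) if (items[j] >= 2) cnt <- cnt + 1L
  if (items[9] >= 1) cnt <- cnt + 1L
  cnt >= 5 && (items[1] >= 2 || items[2] >= 2)
}

oracle_cts5 <- function(items, abuse_cut = 2, loved_cut = 1) {
  flags <- logical(0)
  for (j in 1:4) {
    if (!is.na(items[j])) flags <- c(flags, items[j] >= abuse_cut)
  }
  if (!is.na(items[5])) flags <- c(flags, items[5] <= loved_cut)
  if (length(flags) == 0) return(NA)
  any(flags)
}

oracle_brs <- function(items) {
  if (any(is.na(items))) return(list(mean = NA_real_, low = NA))
  vals <- numeric(6)
  for (j in 1:6) {
    vals[j] <- if (j %% 2 == 0) 6 - items[j] else items[j]
  }
  m <- mean(vals)
  list(mean = m, low = m < 3)
}

# tri-state helpers for the phenotype oracles
.o_known <- function(x) !is.na(x)

# depression: screeners low/anh, six probes, impairment 0-3
oracle_depression <- function(low, anh, probes, imp) {
  low <- .o_val(low); anh <- .o_val(anh); imp <- .o_val(imp)
  probes <- vapply(probes, .o_val, integer(1))
  syms <- c(low, anh, probes)
  n_yes <- sum(syms == 1, na.rm = TRUE)
  n_pos <- n_yes + sum(is.na(syms))
  gate_yes <- (isTRUE(low == 1) || isTRUE(anh == 1))
  gate_no <- isTRUE(low == 0) && isTRUE(anh == 0)
  imp_ok <- if (is.na(imp)) NA else imp >= 2
  if (gate_no) return(FALSE)
  if (n_pos < 5) return(FALSE)
  if (isFALSE(imp_ok)) return(FALSE)
  if (gate_yes && n_yes >= 5 && isTRUE(imp_ok)) return(TRUE)
  NA
}

oracle_bipolar <- function(elation, irrit, syms, dur) {
  elation <- .o_val(elation); irrit <- .o_val(irrit); dur <- .o_val(dur)
  syms <- vapply(syms, .o_val, integer(1))
  gate_yes <- isTRUE(elation == 1) || isTRUE(irrit == 1)
  gate_no <- isTRUE(elation == 0) && isTRUE(irrit == 0)
  n_yes <- sum(syms == 1, na.rm = TRUE)
  n_pos <- n_yes + sum(is.na(syms))
  dur_ok <- if (is.na(dur)) NA else dur >= 2
  if (gate_no) return(FALSE)
  if (n_pos < 3) return(FALSE)
  if (isFALSE(dur_ok)) return(FALSE)
  if (gate_yes && n_yes >= 3 && isTRUE(dur_ok)) return(TRUE)
  NA
}

oracle_panic <- function(gate, syms, rec, unex, worry) {
  gate <- .o_val(gate); rec <- .o_val(rec); unex <- .o_val(unex)
  worry <- .o_val(worry)
  syms <- vapply(syms, .o_val, integer(1))
  n_yes <- sum(syms == 1, na.rm = TRUE)
  n_pos <- n_yes + sum(is.na(syms))
  attack <- if (isTRUE(gate == 0) || n_pos < 4) {
    FALSE
  } else if (isTRUE(gate == 1) && n_yes >= 4) {
    TRUE
  } else {
    NA
  }
  conds <- c(rec, unex, worry)
  disorder <- if (isFALSE(attack) || any(conds == 0, na.rm = TRUE)) {
    FALSE
  } else if (isTRUE(attack) && all(!is.na(conds)) && all(conds == 1)) {
    TRUE
  } else {
    NA
  }
  list(attack = attack, disorder = disorder)
}

oracle_isolation <- function(a, b, v) {
  vals <- vapply(c(a, b, v), .o_val, integer(1))
  n_yes <- sum(vals == 1, na.rm = TRUE)
  n_pos <- n_yes + sum(is.na(vals))
  if (n_yes >= 2) TRUE else if (n_pos < 2) FALSE else NA
}

oracle_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# draw a random item value from a domain extended with NA and skip codes
r_item <- function(n, domain, p_na = 0.1, p_skip = 0.1) {
  pool <- c(domain, NA_integer_, SKIP)
  probs <- c(rep((1 - p_na - p_skip) / length(domain), length(domain)),
             p_na, p_skip)
  sample(pool, n, replace = TRUE, prob = probs)
}
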