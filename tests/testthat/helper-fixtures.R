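# shared fixture builders

perfect_rates <- function() {
  nm <- names(cohort_config()$sensitivity$MHQ1)
  stats::setNames(rep(1, length(nm)), nm)
}

# noise-free study conditions: perfect reporting, no missingness, full
# completion
clean_config <- function(n, seed, ...) {
  cohort_config(
    n_participants = n, seed = seed,
    sensitivity = list(MHQ1 = perfect_rates(), MHQ2 = perfect_rates()),
    specificity = list(MHQ1 = perfect_rates(), MHQ2 = perfect_rates()),
    item_missingness_rate = 0, completion_rate = 1, ...
  )
}

# a minimal hand-rolled dictionary: gate g routes items s1, s2
tiny_dictionary <- function() {
  items <- data.frame(
    item = c("g", "s1", "s2"),
    module = "m1",
    prompt = c("gate", "probe one", "probe two"),
    min = 0L, max = 1L, extra = "",
    parents = c("", "g", "g"),
    ask = c("", "1", "1"),
    waves = "both",
    stringsAsFactors = FALSE
  )
  new_dictionary(items)
}

# wide single-row response frame for direct phenotype-function calls
dep_row <- function(low = 0L, anh = 0L, probes = rep(0L, 6), imp = 0L,
                    onset = NA_integer_) {
  tibble::tibble(
    pid = "p1", dep_screen_low = low, dep_screen_anh = anh,
    dep_sym_tired = probes[1], dep_sym_appetite = probes[2],
    dep_sym_sleep = probes[3], dep_sym_concentration = probes[4],
    dep_sym_worthless = probes[5], dep_sym_death = probes[6],
    dep_impair = imp, dep_onset_year = onset
  )
}
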