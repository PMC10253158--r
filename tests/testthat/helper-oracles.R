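# Independent oracles used to freeze expected values.

# Daily stock simulation of medication availability: each day, supplies
# dispensed that day join the stock; if stock >= 1 the day is covered and
# one dose is consumed. For whole-day supplies this equals carry-over
# interval arithmetic, but computed by enumeration rather than sweeping.
oracle_cma_stock <- function(dates, supply, window) {
  n_days <- as.integer(window[2] - window[1])
  stock <- 0
  covered <- 0L
  for (d in seq_len(n_days) - 1L) {
    stock <- stock + sum(supply[dates == window[1] + d])
    if (stock >= 1) {
      stock <- stock - 1
      covered <- covered + 1L
    }
  }
  covered / n_days * 100
}

# Textbook Pearson chi-square: sum (O - E)^2 / E with E from the margins.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Textbook one-way ANOVA from sums of squares.
oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - mean(y))^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  dfb <- length(groups) - 1L
  dfw <- length(y) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# A minimal well-formed dispensing tibble for unit tests.
make_records <- function(patient_id, dispense_date, atc_code,
                         ddd_total = 28, gender = "male",
                         birth_date = as.Date("1960-06-15")) {
  tibble::tibble(
    patient_id = patient_id,
    birth_date = birth_date,
    gender = gender,
    dispense_date = as.Date(dispense_date),
    atc_code = atc_code,
    n_packages = 1L,
    ddd_total = ddd_total,
    active_ingredient = NA_character_,
    medication_name = NA_character_
  )
}

# Regular refill schedule as a records tibble.
refill_records <- function(patient_id, from, to, gap, atc = "A10BA02",
                           ddd_total = 28, ...) {
  dates <- seq(as.Date(from), as.Date(to), by = gap)
  make_records(patient_id, dates, atc, ddd_total = ddd_total, ...)
}
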