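#' Continuous multiple-interval measure of medication availability (CMA)
#'
#' Computes the fraction of an observation window covered by dispensed
#' supply, as a percentage. Under the default carry-over variant the
#' dispensations are swept in date order and each supply interval starts at
#' the later of its dispensation date and the exhaustion of all previously
#' accumulated supply — an early refill is shelved, never lost — and
#' coverage is truncated at the window end, so the result cannot exceed
#' 100. The `simple_ratio` variant is the crude sum of days supplied over
#' window length (capped at 100 unless `cap_at_100` is off); the two agree
#' whenever no supply intervals overlap and none crosses the window end.
#'
#' The window is closed on the left and open on the right: a dispensation on
#' the window's last day contributes no covered days.
#'
#' @param dispense_date `Date` vector of dispensation dates, any order.
#' @param days_supplied Numeric vector of per-dispensation days of supply
#'   (may be fractional).
#' @param window Length-2 `Date`: observation window
#'   `[window_start, window_end)`; typically index date to follow-up end.
#' @param cfg An [adherence_config()].
#' @return A list: `cma_percent`, `covered_days`, `window_days`, `stratum`.
#' @examples
#' compute_cma(as.Date("2020-01-01"), 30,
#'             window = as.Date(c("2020-01-01", "2020-04-10")))
#' @export
compute_cma <- function(dispense_date, days_supplied, window,
                        cfg = adherence_config()) {
  stopifnot(inherits(window, "Date"), length(window) == 2L)
  window_days <- as.numeric(window[2] - window[1])
  if (window_days < 1) stop("observation window shorter than one day", call. = FALSE)
  if (any(days_supplied < 0)) stop("negative days of supply", call. = FALSE)
  keep <- dispense_date >= window[1] & dispense_date < window[2]
  dispense_date <- dispense_date[keep]
  days_supplied <- days_supplied[keep]

  if (cfg$variant == "carryover") {
    ord <- order(dispense_date)
    t <- as.numeric(dispense_date[ord] - window[1])
    s <- days_supplied[ord]
    covered <- 0
    avail_end <- 0                      # exhaustion time of accumulated supply
    for (i in seq_along(t)) {
      start <- max(t[i], avail_end)
      avail_end <- start + s[i]
      covered <- covered + max(0, min(avail_end, window_days) - min(start, window_days))
    }
  } else {
    covered <- sum(days_supplied)
    if (cfg$cap_at_100) covered <- min(covered, window_days)
  }
  cma <- covered / window_days * 100
  if (cfg$cap_at_100) cma <- min(cma, 100)
  list(cma_percent = cma, covered_days = covered, window_days = window_days,
       stratum = stratify_adherence(cma, cfg))
}

#' Adherence stratum of a CMA value
#'
#' Bands are closed at their lower edge: adherent when CMA >= 80, partially
#' adherent when 40 <= CMA < 80, non-adherent when CMA < 40 (defaults).
#'
#' @param cma_percent Numeric vector of CMA percentages.
#' @param cfg An [adherence_config()].
#' @return Character vector in
#'   `c("adherent", "partially_adherent", "non_adherent")`.
#' @export
stratify_adherence <- function(cma_percent, cfg = adherence_config()) {
  dplyr::case_when(
    cma_percent >= cfg$adherent_threshold ~ "adherent",
    cma_percent >= cfg$partial_threshold ~ "partially_adherent",
    .default = "non_adherent"
  )
}

#' Per-patient CMA over a cohort
#'
#' Pools each patient's antidiabetic dispensations into a single supply
#' stream and computes one CMA over the follow-up window
#' `[index_date, follow_up_end)`.
#'
#' @param cohort Cohort tibble from [select_naive_cohort()] (or its
#'   metformin refinement).
#' @param records Dispensing records; only antidiabetic rows are used.
#' @param cfg An [adherence_config()].
#' @return Tibble: `patient_id`, `window_start`, `window_end`,
#'   `covered_days`, `window_days`, `cma_percent`, `stratum`, plus the
#'   cohort's `subgroup` and `gender`.
#' @export
cohort_adherence <- function(cohort, records, cfg = adherence_config()) {
  ads <- records[is_antidiabetic(records$atc_code), , drop = FALSE]
  ads <- ads[ads$patient_id %in% cohort$patient_id, , drop = FALSE]
  split_ads <- split(ads[, c("dispense_date", "ddd_total")], ads$patient_id)
  res <- purrr::pmap(
    list(cohort$patient_id, cohort$index_date, cohort$follow_up_end),
    function(pid, start, end) {
      ev <- split_ads[[pid]]
      r <- compute_cma(ev$dispense_date, days_supplied(ev$ddd_total),
                       window = c(start, end), cfg = cfg)
      tibble::tibble(patient_id = pid, window_start = start,
                     window_end = end, covered_days = r$covered_days,
                     window_days = r$window_days,
                     cma_percent = r$cma_percent, stratum = r$stratum)
    })
  dplyr::bind_rows(res) |>
    dplyr::left_join(cohort[, c("patient_id", "subgroup", "gender")],
                     by = "patient_id")
}

#' Adherence summary by subgroup
#'
#' Median CMA with interquartile range per subgroup, overall and by gender,
#' stratum percentages per subgroup, and a cross-subgroup summary: the mean
#' of the per-subgroup median CMAs excluding the monotherapy subgroup.
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param adherence Tibble from [cohort_adherence()] (columns `cma_percent`,
#'   `stratum`, `subgroup`, `gender`).
#' @return A list of tibbles: `by_subgroup` (overall and per-gender median
#'   [IQR]), `strata` (stratum percentages per subgroup), and
#'   `cross_subgroup` with `mean_median_cma_excl_monotherapy`.
#' @export
adherence_table <- function(adherence) {
  empty <- !nrow(adherence)
  if (empty) {
    warning("no adherence results; empty summary", call. = FALSE)
  }
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
  }
  by_subgroup <- adherence |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::reframe(gender = "all", med_iqr(.data$cma_percent))
  by_gender <- adherence |>
    dplyr::group_by(.data$subgroup, .data$gender) |>
    dplyr::reframe(med_iqr(.data$cma_percent))
  strata <- adherence |>
    dplyr::count(.data$subgroup, .data$stratum) |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::mutate(percent = .round_half_up(.data$n / sum(.data$n) * 100, 1)) |>
    dplyr::ungroup()
  non_mono <- by_subgroup[by_subgroup$subgroup != "1", , drop = FALSE]
  cross <- tibble::tibble(
    mean_median_cma_excl_monotherapy =
      if (nrow(non_mono)) mean(non_mono$median) else NA_real_
  )
  list(by_subgroup = dplyr::bind_rows(by_subgroup, by_gender) |>
         dplyr::arrange(.data$subgroup, .data$gender),
       strata = strata,
       cross_subgroup = cross)
}
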