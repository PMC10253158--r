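#' Study configuration
#'
#' Bundles every date window and rule threshold of the new-user design: the
#' data-collection window, the wash-out year that must be free of
#' antidiabetic dispensations, the index year in which the first
#' antidiabetic dispensation must fall, the age rule, the per-year
#' dispensing-frequency filter, and the combination-initiator window.
#'
#' @param data_window Length-2 `Date`: first and last day of data collection.
#' @param washout_year Calendar year that must contain no antidiabetic
#'   dispensation for a patient to count as treatment-naive.
#' @param index_year Calendar year of the index period.
#' @param age_reference_date Date at which age is computed (completed years).
#' @param min_age_years Minimum age at `age_reference_date`.
#' @param min_index_year_dispensations Minimum antidiabetic dispensations in
#'   the index year.
#' @param min_follow_up_dispensations_per_year Minimum antidiabetic
#'   dispensations required in each complete calendar year after the index
#'   year, the chronic-use filter.
#' @param combination_window_days A metformin initiator dispensed a second
#'   distinct antidiabetic within this many days of the index date (window
#'   inclusive of both ends) is a first-line combination-therapy initiator.
#' @param discontinuation_gap_days A switcher whose last antidiabetic supply
#'   runs out at least this many days before the study end, with no further
#'   dispensation, is classed as having discontinued after switching.
#' @return A list of class `"rx_study_config"`.
#' @export
study_config <- function(data_window = as.Date(c("2018-01-01", "2021-12-31")),
                         washout_year = 2018L,
                         index_year = 2019L,
                         age_reference_date = as.Date("2021-12-31"),
                         min_age_years = 18L,
                         min_index_year_dispensations = 1L,
                         min_follow_up_dispensations_per_year = 2L,
                         combination_window_days = 9L,
                         discontinuation_gap_days = 90L) {
  stopifnot(
    inherits(data_window, "Date"), length(data_window) == 2L,
    data_window[1] < data_window[2],
    washout_year < index_year,
    combination_window_days >= 0,
    discontinuation_gap_days >= 0,
    min_age_years >= 0
  )
  yrs <- as.integer(format(data_window, "%Y"))
  if (washout_year < yrs[1] || index_year > yrs[2]) {
    stop("washout/index years must lie inside the data window", call. = FALSE)
  }
  structure(list(
    data_window = data_window,
    washout_year = as.integer(washout_year),
    index_year = as.integer(index_year),
    age_reference_date = age_reference_date,
    min_age_years = as.integer(min_age_years),
    min_index_year_dispensations = as.integer(min_index_year_dispensations),
    min_follow_up_dispensations_per_year = as.integer(min_follow_up_dispensations_per_year),
    combination_window_days = as.integer(combination_window_days),
    discontinuation_gap_days = as.integer(discontinuation_gap_days),
    index_drug_atc = "A10",
    first_line_drug = ATC_METFORMIN
  ), class = "rx_study_config")
}

#' Adherence configuration
#'
#' @param variant `"carryover"` (default): supply intervals are swept in
#'   date order and an early refill is shelved until the previous supply is
#'   exhausted, so coverage never exceeds the window. `"simple_ratio"`: the
#'   crude sum of days supplied over window length.
#' @param cap_at_100 Cap the reported CMA at 100 percent (default `TRUE`;
#'   only the simple ratio can exceed it).
#' @param adherent_threshold CMA percentage at or above which a patient is
#'   adherent (default 80).
#' @param partial_threshold CMA percentage at or above which a patient is at
#'   least partially adherent (default 40).
#' @return A list of class `"rx_adherence_config"`.
#' @export
adherence_config <- function(variant = c("carryover", "simple_ratio"),
                             cap_at_100 = TRUE,
                             adherent_threshold = 80,
                             partial_threshold = 40) {
  variant <- match.arg(variant)
  stopifnot(partial_threshold > 0, partial_threshold < adherent_threshold,
            adherent_threshold <= 100)
  structure(list(variant = variant, cap_at_100 = isTRUE(cap_at_100),
                 adherent_threshold = adherent_threshold,
                 partial_threshold = partial_threshold),
            class = "rx_adherence_config")
}

# completed years between two dates (birthday not yet reached => year less)
.age_completed_years <- function(birth_date, ref_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ry <- as.integer(format(ref_date, "%Y"))
  bday <- suppressWarnings(as.Date(paste0(ry, format(birth_date, "-%m-%d"))))
  # Feb 29 birthdays roll to Mar 1 in non-leap years
  bday[is.na(bday)] <- as.Date(paste0(ry, "-03-01"))
  ry - by - as.integer(bday > ref_date)
}

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

.year_of <- function(d) as.integer(format(d, "%Y"))
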