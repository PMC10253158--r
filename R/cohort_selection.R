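#' Select the treatment-naive antidiabetic cohort
#'
#' Applies the new-user selection algorithm to a dispensing stream and a
#' death registry. A patient is retained when all of the following hold, and
#' excluded at the first failure in this order:
#'
#' 1. **age** — at least `min_age_years` completed years at
#'    `age_reference_date`;
#' 2. **wash-out** — no antidiabetic (ATC A10) dispensation before 1 January
#'    of the index year;
#' 3. **index year** — first antidiabetic dispensation falls in the index
#'    year, with at least `min_index_year_dispensations` that year;
#' 4. **follow-up frequency** — at least
#'    `min_follow_up_dispensations_per_year` antidiabetic dispensations in
#'    each complete calendar year after the index year inside the data
#'    window (the chronic-treatment filter);
#' 5. **death** — not present in the death registry with a death date on or
#'    before the study end.
#'
#' Follow-up runs from the index date to the patient's last antidiabetic
#' dispensation or the study end, whichever is earlier.
#'
#' @param records Tibble of dispensing records (all drugs, not only
#'   antidiabetics).
#' @param deaths Tibble with columns `patient_id`, `death_date`, or `NULL`.
#' @param cfg A [study_config()].
#' @return A list with elements
#'   \describe{
#'     \item{cohort}{tibble, one row per retained patient: `patient_id`,
#'       `birth_date`, `gender`, `index_date`, `index_drugs`
#'       (list-column of ATC-5 codes dispensed on the index date),
#'       `n_index_drugs`, `follow_up_end`, `n_distinct_ads`, `subgroup`.}
#'     \item{ledger}{tibble `patient_id`, `reason` — one row per excluded
#'       patient, first failed criterion only.}
#'   }
#' @export
select_naive_cohort <- function(records, deaths = NULL, cfg = study_config()) {
  if (nrow(records) == 0L) {
    return(list(cohort = .empty_cohort(), ledger = tibble::tibble(
      patient_id = character(), reason = character())))
  }
  study_end <- cfg$data_window[2]
  ads <- records[is_antidiabetic(records$atc_code), , drop = FALSE]

  patients <- records |>
    dplyr::distinct(.data$patient_id, .data$birth_date, .data$gender) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$patient_id)

  per <- ads |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_ad = min(.data$dispense_date),
      last_ad = max(.data$dispense_date),
      n_index_year = sum(.year_of(.data$dispense_date) == cfg$index_year),
      .groups = "drop"
    )
  fu_years <- if (.year_of(study_end) > cfg$index_year) {
    seq(cfg$index_year + 1L, .year_of(study_end))
  } else integer()
  if (length(fu_years)) {
    fu_counts <- ads |>
      dplyr::filter(.year_of(.data$dispense_date) %in% fu_years) |>
      dplyr::count(.data$patient_id, year = .year_of(.data$dispense_date)) |>
      tidyr::complete(patient_id = per$patient_id, year = fu_years,
                      fill = list(n = 0L)) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(min_per_year = min(.data$n), .groups = "drop")
  } else {
    fu_counts <- tibble::tibble(patient_id = per$patient_id,
                                min_per_year = Inf)
  }

  tab <- patients |>
    dplyr::left_join(per, by = "patient_id") |>
    dplyr::left_join(fu_counts, by = "patient_id")
  tab$min_per_year[is.na(tab$min_per_year)] <- 0L
  if (!is.null(deaths) && nrow(deaths)) {
    tab <- dplyr::left_join(tab, deaths, by = "patient_id")
  } else {
    tab$death_date <- as.Date(NA)
  }

  age <- .age_completed_years(tab$birth_date, cfg$age_reference_date)
  index_start <- as.Date(paste0(cfg$index_year, "-01-01"))

  reason <- rep(NA_character_, nrow(tab))
  fail <- function(cond, why) reason[is.na(reason) & cond] <<- why
  fail(age < cfg$min_age_years, "age")
  fail(!is.na(tab$first_ad) & tab$first_ad < index_start, "wash-out")
  fail(is.na(tab$first_ad) |
         .year_of(tab$first_ad) != cfg$index_year |
         tab$n_index_year < cfg$min_index_year_dispensations,
       "index-year")
  fail(tab$min_per_year < cfg$min_follow_up_dispensations_per_year,
       "follow-up frequency")
  fail(!is.na(tab$death_date) & tab$death_date <= study_end, "death")

  ledger <- tibble::tibble(patient_id = tab$patient_id[!is.na(reason)],
                           reason = reason[!is.na(reason)])
  kept <- tab[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(cohort = .empty_cohort(), ledger = ledger))
  }

  kept_ads <- ads[ads$patient_id %in% kept$patient_id, , drop = FALSE]
  idx <- kept_ads |>
    dplyr::inner_join(kept[, c("patient_id", "first_ad")], by = "patient_id") |>
    dplyr::filter(.data$dispense_date == .data$first_ad) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_drugs = list(sort(unique(.data$atc_code))),
                     .groups = "drop")

  nads <- kept_ads |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_distinct_ads = dplyr::n_distinct(.data$atc_code),
                     .groups = "drop")

  cohort <- kept |>
    dplyr::transmute(.data$patient_id, .data$birth_date, .data$gender,
                     index_date = .data$first_ad,
                     follow_up_end = pmin(.data$last_ad, study_end)) |>
    dplyr::left_join(idx, by = "patient_id") |>
    dplyr::left_join(nads, by = "patient_id") |>
    dplyr::mutate(n_index_drugs = lengths(.data$index_drugs),
                  subgroup = ad_subgroup(.data$n_distinct_ads)) |>
    dplyr::select("patient_id", "birth_date", "gender", "index_date",
                  "index_drugs", "n_index_drugs", "follow_up_end",
                  "n_distinct_ads", "subgroup") |>
    dplyr::arrange(.data$patient_id)

  list(cohort = cohort, ledger = ledger)
}

.empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(), birth_date = as.Date(character()),
    gender = character(), index_date = as.Date(character()),
    index_drugs = list(), n_index_drugs = integer(),
    follow_up_end = as.Date(character()), n_distinct_ads = integer(),
    subgroup = character()
  )
}

#' Index event of a treatment-naive patient
#'
#' The index date is the date of the first antidiabetic dispensation in the
#' index year; the index drugs are all distinct antidiabetic ATC-5 codes
#' dispensed that day (multiple same-day starters are a reported category).
#'
#' @param records Dispensing records of one patient.
#' @param cfg A [study_config()].
#' @return A list with `patient_id`, `index_date`, `index_drugs`.
#' @export
find_index_event <- function(records, cfg = study_config()) {
  stopifnot(dplyr::n_distinct(records$patient_id) == 1L)
  ad <- records[is_antidiabetic(records$atc_code), , drop = FALSE]
  in_index <- ad[.year_of(ad$dispense_date) == cfg$index_year, , drop = FALSE]
  if (nrow(in_index) == 0L) {
    stop("patient has no antidiabetic dispensation in the index year",
         call. = FALSE)
  }
  if (any(ad$dispense_date < as.Date(paste0(cfg$index_year, "-01-01")))) {
    stop("patient is not treatment-naive: antidiabetic dispensation before the index year",
         call. = FALSE)
  }
  index_date <- min(in_index$dispense_date)
  list(patient_id = records$patient_id[[1]],
       index_date = index_date,
       index_drugs = sort(unique(in_index$atc_code[in_index$dispense_date == index_date])))
}

#' Refine the cohort to metformin monotherapy initiators
#'
#' Restricts the selected cohort to patients whose sole index drug is plain
#' metformin, then removes first-line combination-therapy initiators: any
#' member dispensed a second distinct antidiabetic (different ATC-5 code)
#' within `combination_window_days` of the index date, window inclusive of
#' day 0 and the last day.
#'
#' @param cohort The `cohort` tibble from [select_naive_cohort()].
#' @param records The dispensing records the cohort was selected from.
#' @param cfg A [study_config()].
#' @return List with `metformin_cohort` and `combination_initiators`
#'   tibbles (same columns as `cohort`).
#' @export
refine_metformin_cohort <- function(cohort, records, cfg = study_config()) {
  sole_met <- vapply(cohort$index_drugs, function(d)
    length(d) == 1L && d == cfg$first_line_drug, logical(1))
  met <- cohort[sole_met, , drop = FALSE]
  if (nrow(met) == 0L) {
    return(list(metformin_cohort = met, combination_initiators = met))
  }
  ads <- records[is_antidiabetic(records$atc_code) &
                   records$patient_id %in% met$patient_id, , drop = FALSE]
  win <- ads |>
    dplyr::inner_join(met[, c("patient_id", "index_date")], by = "patient_id") |>
    dplyr::filter(.data$atc_code != cfg$first_line_drug,
                  .data$dispense_date >= .data$index_date,
                  .data$dispense_date <= .data$index_date + cfg$combination_window_days)
  combo_ids <- unique(win$patient_id)
  list(
    metformin_cohort = met[!met$patient_id %in% combo_ids, , drop = FALSE],
    combination_initiators = met[met$patient_id %in% combo_ids, , drop = FALSE]
  )
}

#' Subgroup by number of distinct antidiabetics
#'
#' Cohort members are grouped by how many distinct antidiabetic ATC-5 codes
#' they were dispensed during follow-up: 1, 2, 3, 4, or "5+" for five or
#' more.
#'
#' @param n_distinct_ads Positive integer vector.
#' @return Character vector with levels `"1" "2" "3" "4" "5+"`.
#' @export
ad_subgroup <- function(n_distinct_ads) {
  stopifnot(all(n_distinct_ads >= 1L))
  ifelse(n_distinct_ads >= 5L, "5+", as.character(n_distinct_ads))
}
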