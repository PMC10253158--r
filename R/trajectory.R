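#' Classify the first treatment intensification of a metformin initiator
#'
#' For a metformin monotherapy initiator (combination initiators already
#' removed), the first change in antidiabetic therapy is the first
#' dispensation of a non-metformin antidiabetic after the combination
#' window. Categories:
#'
#' * **monotherapy** — no such dispensation during follow-up;
#' * **add_on** — the new drug is a metformin-containing fixed-dose
#'   combination, or plain metformin is dispensed again on or after the new
#'   drug's start (the second drug joins continuing metformin);
#' * **switch** — no metformin dispensation on or after the change date
#'   (the new drug replaces metformin);
#' * **switch_then_discontinue** — a switch after which the patient's last
#'   antidiabetic supply runs out at least `discontinuation_gap_days` before
#'   the study end, with no further dispensation.
#'
#' Only the first change is classified; later additions feed the
#' distinct-antidiabetic count but not the label.
#'
#' @param records Dispensing records of one patient (non-antidiabetic rows
#'   are ignored).
#' @param index_date The patient's index date.
#' @param cfg A [study_config()].
#' @return A list: `category`, `change_date` (`NA` for monotherapy),
#'   `change_atc` (`NA` for monotherapy).
#' @export
classify_first_intensification <- function(records, index_date,
                                           cfg = study_config()) {
  ad <- records[is_antidiabetic(records$atc_code), , drop = FALSE]
  if (nrow(ad) == 0L) stop("empty antidiabetic timeline", call. = FALSE)
  ad <- ad[order(ad$dispense_date, ad$atc_code), , drop = FALSE]
  met <- cfg$first_line_drug

  other <- ad[ad$atc_code != met &
                ad$dispense_date > index_date + cfg$combination_window_days, ,
              drop = FALSE]
  if (nrow(other) == 0L) {
    return(list(category = "monotherapy", change_date = as.Date(NA),
                change_atc = NA_character_))
  }
  change_date <- other$dispense_date[[1]]
  change_atc <- other$atc_code[[1]]

  if (is_metformin_fdc(change_atc) ||
      any(ad$atc_code == met & ad$dispense_date >= change_date)) {
    return(list(category = "add_on", change_date = change_date,
                change_atc = change_atc))
  }
  # switch; discontinued if the last supply runs out well before study end
  supply_end <- max(as.numeric(ad$dispense_date) + days_supplied(ad$ddd_total))
  gap <- as.numeric(cfg$data_window[2]) - supply_end
  category <- if (gap >= cfg$discontinuation_gap_days)
    "switch_then_discontinue" else "switch"
  list(category = category, change_date = change_date, change_atc = change_atc)
}

#' Reporting class of an intensification drug
#'
#' Maps the drug involved in a first therapy change to the class used in
#' reporting: its ATC level-4 class name for plain agents, the named
#' component pair for metformin fixed-dose combinations (A10BD), and a
#' single "insulins alone or in combination" roll-up for all insulins
#' (A10A).
#'
#' @param atc_code Character vector of antidiabetic ATC-5 codes.
#' @return Character vector of reporting-class labels.
#' @examples
#' intensification_class(c("A10BB09", "A10BD07", "A10AB05"))
#' @export
intensification_class <- function(atc_code) {
  if (any(!is_antidiabetic(atc_code))) {
    stop("non-antidiabetic code passed to intensification_class", call. = FALSE)
  }
  vapply(atc_code, function(code) {
    if (startsWith(code, "A10A")) {
      unname(atc_ad_class_names[["A10A"]])
    } else if (startsWith(code, "A10BD")) {
      comp <- atc_fdc_components$components[
        match(code, atc_fdc_components$atc_code)]
      paste0("fixed-dose combinations (",
             ifelse(is.na(comp), code, comp), ")")
    } else {
      l4 <- atc_prefix(code, 4)
      name <- atc_ad_class_names[l4]
      ifelse(is.na(name), l4, unname(name))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Classify trajectories over a cohort
#'
#' Applies [classify_first_intensification()] to every member of a
#' metformin cohort.
#'
#' @param cohort Metformin cohort tibble (from [refine_metformin_cohort()]).
#' @param records Dispensing records.
#' @param cfg A [study_config()].
#' @return Tibble: `patient_id`, `category`, `change_date`, `change_atc`,
#'   `reporting_class`, `subgroup`.
#' @export
classify_trajectories <- function(cohort, records, cfg = study_config()) {
  ads <- records[is_antidiabetic(records$atc_code) &
                   records$patient_id %in% cohort$patient_id, , drop = FALSE]
  by_pat <- split(ads, ads$patient_id)
  res <- purrr::map2(cohort$patient_id, cohort$index_date, function(pid, idx) {
    lab <- classify_first_intensification(by_pat[[pid]], idx, cfg)
    tibble::tibble(patient_id = pid, category = lab$category,
                   change_date = lab$change_date, change_atc = lab$change_atc)
  })
  out <- dplyr::bind_rows(res)
  out$reporting_class <- NA_character_
  chg <- !is.na(out$change_atc)
  if (any(chg)) {
    out$reporting_class[chg] <- intensification_class(out$change_atc[chg])
  }
  dplyr::left_join(out, cohort[, c("patient_id", "subgroup")], by = "patient_id")
}

#' Summarise first-intensification outcomes
#'
#' Counts and percentages per category (and per reporting class) over the
#' two-antidiabetic subgroup, the set in which the first change is the whole
#' trajectory. Percentages are count over subgroup size, rounded half-up to
#' one decimal.
#'
#' @param trajectories Tibble from [classify_trajectories()].
#' @param subgroup Which subgroup to summarise (default `"2"`).
#' @return List of tibbles `by_category` and `by_class`.
#' @export
intensification_summary <- function(trajectories, subgroup = "2") {
  sub <- trajectories[trajectories$subgroup == subgroup, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L || all(sub$category == "monotherapy")) {
    warning("no intensification events in subgroup ", subgroup, call. = FALSE)
    return(list(by_category = tibble::tibble(category = character(),
                                             n = integer(), percent = numeric()),
                by_class = tibble::tibble(category = character(),
                                          reporting_class = character(),
                                          n = integer(), percent = numeric())))
  }
  by_category <- sub |>
    dplyr::count(.data$category) |>
    dplyr::mutate(percent = .round_half_up(.data$n / !!n * 100, 1))
  by_class <- sub |>
    dplyr::filter(.data$category != "monotherapy") |>
    dplyr::count(.data$category, .data$reporting_class) |>
    dplyr::mutate(percent = .round_half_up(.data$n / !!n * 100, 1))
  list(by_category = by_category, by_class = by_class)
}
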