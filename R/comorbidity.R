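#' Load an Rx-Risk condition map
#'
#' The Rx-Risk comorbidity index infers treated conditions purely from
#' dispensed drug classes: one qualifying dispensation marks the patient as
#' on treatment for that condition. This adaptation maps conditions to ATC
#' level-2 (ATCL2) code sets and tags each as diabetes-concordant (shared
#' pathophysiology and management goals) or discordant. The default map
#' ships with the package; a custom map with the same columns
#' (`condition`, `codes`, `concordance`) can be supplied.
#'
#' Compact ranges in `codes` (e.g. `"J01-J07"`, `"A08-A09, A11-A16"`) are
#' expanded lexicographically within one letter prefix at load time.
#'
#' @param path Path to a CSV map; default is the packaged map.
#' @return Tibble with one row per (condition, ATCL2 code):
#'   `condition`, `atcl2`, `concordance`.
#' @export
rx_risk_map <- function(path = system.file("extdata", "rx_risk_atcl2.csv",
                                           package = "rxcohort")) {
  raw <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("condition", "codes", "concordance") %in% names(raw)))
  map <- raw |>
    dplyr::mutate(atcl2 = purrr::map(.data$codes, expand_atcl2_codes)) |>
    tidyr::unnest("atcl2") |>
    dplyr::select("condition", "atcl2", "concordance")
  if (anyDuplicated(map$atcl2)) {
    stop("ATCL2 code(s) mapped to more than one condition: ",
         paste(unique(map$atcl2[duplicated(map$atcl2)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(unique(raw$condition)) || anyDuplicated(raw$condition)) {
    stop("duplicate condition names in map", call. = FALSE)
  }
  map
}

#' Expand a compact ATCL2 code specification
#'
#' `"C02, C03, C09"` lists codes; `"J01-J07"` is a lexicographic range
#' within one letter prefix; the two combine freely.
#'
#' @param spec A single character string.
#' @return Character vector of 3-character ATCL2 codes.
#' @export
expand_atcl2_codes <- function(spec) {
  parts <- trimws(strsplit(spec, ",")[[1]])
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ends <- trimws(strsplit(p, "-", fixed = TRUE)[[1]])
      stopifnot(length(ends) == 2L,
                substr(ends[1], 1, 1) == substr(ends[2], 1, 1))
      nums <- as.integer(substr(ends, 2, 3))
      sprintf("%s%02d", substr(ends[1], 1, 1), seq(nums[1], nums[2]))
    } else {
      p
    }
  })
  codes <- unlist(out)
  if (!all(grepl("^[A-Z][0-9]{2}$", codes))) {
    stop("invalid ATCL2 code(s) in spec: ", spec, call. = FALSE)
  }
  codes
}

#' Flag comorbidities from dispensed drug classes
#'
#' A condition is flagged for a patient when at least one non-antidiabetic
#' dispensation in the window has an ATCL2 prefix in the condition's code
#' set. Antidiabetic (A10) dispensations never contribute: the index
#' profiles comorbidities of diabetes, not diabetes itself.
#'
#' @param records Dispensing records (any patients).
#' @param map Tibble from [rx_risk_map()].
#' @param window Optional length-2 `Date`; defaults to all records (the
#'   whole study period).
#' @return Tibble, one row per (patient, flagged condition):
#'   `patient_id`, `condition`, `concordance`. Patients with no flagged
#'   condition have no rows.
#' @export
assign_comorbidities <- function(records, map = rx_risk_map(), window = NULL) {
  rec <- records
  if (!is.null(window)) {
    rec <- rec[rec$dispense_date >= window[1] & rec$dispense_date <= window[2], ,
               drop = FALSE]
  }
  rec <- rec[!is_antidiabetic(rec$atc_code), , drop = FALSE]
  if (!nrow(rec)) {
    return(tibble::tibble(patient_id = character(), condition = character(),
                          concordance = character()))
  }
  rec$atcl2 <- atc_prefix(rec$atc_code, 2)
  rec |>
    dplyr::inner_join(map, by = "atcl2", relationship = "many-to-many") |>
    dplyr::distinct(.data$patient_id, .data$condition, .data$concordance)
}

#' ATC level-1 drug-group usage by subgroup
#'
#' Percentage of patients in each subgroup with at least one
#' non-antidiabetic dispensation in each anatomical main group (ATCL1),
#' keeping only groups reaching `min_prevalence` percent in at least one
#' subgroup.
#'
#' @param cohort Cohort tibble with `patient_id` and `subgroup`.
#' @param records Dispensing records.
#' @param min_prevalence Reporting filter, percent (default 10).
#' @return Tibble: `atcl1`, `subgroup`, `n`, `percent`.
#' @export
atcl1_usage_table <- function(cohort, records, min_prevalence = 10) {
  sizes <- dplyr::count(cohort, .data$subgroup, name = "subgroup_n")
  if (any(sizes$subgroup_n == 0L)) warning("empty subgroup omitted", call. = FALSE)
  rec <- records[records$patient_id %in% cohort$patient_id &
                   !is_antidiabetic(records$atc_code), , drop = FALSE]
  if (!nrow(rec)) {
    return(tibble::tibble(atcl1 = character(), subgroup = character(),
                          n = integer(), percent = numeric()))
  }
  rec$atcl1 <- atc_prefix(rec$atc_code, 1)
  counts <- rec |>
    dplyr::inner_join(cohort[, c("patient_id", "subgroup")], by = "patient_id") |>
    dplyr::distinct(.data$patient_id, .data$subgroup, .data$atcl1) |>
    dplyr::count(.data$atcl1, .data$subgroup)
  tab <- tidyr::crossing(atcl1 = unique(counts$atcl1),
                         subgroup = sizes$subgroup) |>
    dplyr::left_join(counts, by = c("atcl1", "subgroup")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(sizes, by = "subgroup") |>
    dplyr::mutate(percent = .round_half_up(.data$n / .data$subgroup_n * 100, 1))
  keep <- tab |>
    dplyr::group_by(.data$atcl1) |>
    dplyr::summarise(max_prev = max(.data$percent), .groups = "drop") |>
    dplyr::filter(.data$max_prev >= min_prevalence)
  tab |>
    dplyr::semi_join(keep, by = "atcl1") |>
    dplyr::select("atcl1", "subgroup", "n", "percent") |>
    dplyr::arrange(.data$atcl1, .data$subgroup)
}

#' Comorbidity prevalence table by subgroup
#'
#' Percentage of patients in each subgroup flagged with each Rx-Risk
#' condition. Conditions below `min_prevalence` percent in every subgroup
#' are dropped; rows are grouped by concordance and sorted by prevalence in
#' the reference subgroup, descending.
#'
#' @param comorbidities Tibble from [assign_comorbidities()].
#' @param cohort Cohort tibble with `patient_id` and `subgroup`.
#' @param min_prevalence Reporting filter, percent (default 10).
#' @param reference_subgroup Subgroup whose prevalence orders the rows
#'   (default `"1"`).
#' @return Tibble: `concordance`, `condition`, `subgroup`, `n`, `percent`.
#' @export
prevalence_table <- function(comorbidities, cohort, min_prevalence = 10,
                             reference_subgroup = "1") {
  sizes <- dplyr::count(cohort, .data$subgroup, name = "subgroup_n")
  counts <- comorbidities |>
    dplyr::inner_join(cohort[, c("patient_id", "subgroup")], by = "patient_id") |>
    dplyr::count(.data$concordance, .data$condition, .data$subgroup)
  if (!nrow(counts)) {
    return(tibble::tibble(concordance = character(), condition = character(),
                          subgroup = character(), n = integer(),
                          percent = numeric()))
  }
  grid <- tidyr::crossing(
    dplyr::distinct(counts, .data$concordance, .data$condition),
    subgroup = sizes$subgroup)
  tab <- grid |>
    dplyr::left_join(counts, by = c("concordance", "condition", "subgroup")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(sizes, by = "subgroup") |>
    dplyr::mutate(percent = .round_half_up(.data$n / .data$subgroup_n * 100, 1))
  keep <- tab |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(max_prev = max(.data$percent), .groups = "drop") |>
    dplyr::filter(.data$max_prev >= min_prevalence)
  ref <- tab |>
    dplyr::filter(.data$subgroup == reference_subgroup) |>
    dplyr::select("condition", ref_prev = "percent")
  tab |>
    dplyr::semi_join(keep, by = "condition") |>
    dplyr::left_join(ref, by = "condition") |>
    dplyr::arrange(.data$concordance, dplyr::desc(.data$ref_prev),
                   .data$condition, .data$subgroup) |>
    dplyr::select("concordance", "condition", "subgroup", "n", "percent")
}
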