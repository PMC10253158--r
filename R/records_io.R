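#' Table dialect for administrative extracts
#'
#' Administrative dispensing extracts differ in delimiter, date format and
#' column naming. A dialect bundles the three so that readers can map an
#' arbitrary extract onto the canonical schema
#' (`patient_id`, `birth_date`, `gender`, `dispense_date`, `atc_code`,
#' `n_packages`, `ddd_total`, and optionally `active_ingredient`,
#' `medication_name`).
#'
#' @param delim Field delimiter (default comma).
#' @param date_format Date format string understood by [as.Date()]
#'   (default ISO-8601, `"%Y-%m-%d"`).
#' @param col_map Named character vector mapping canonical names to the
#'   file's column names; canonical names absent from the map are assumed to
#'   appear verbatim in the header.
#' @return A list of class `"rx_dialect"`.
#' @export
table_dialect <- function(delim = ",", date_format = "%Y-%m-%d",
                          col_map = character()) {
  stopifnot(is.character(delim), nchar(delim) == 1L)
  structure(list(delim = delim, date_format = date_format,
                 col_map = col_map),
            class = "rx_dialect")
}

.dispensing_cols <- c("patient_id", "birth_date", "gender", "dispense_date",
                      "atc_code", "n_packages", "ddd_total")
.dispensing_opt  <- c("active_ingredient", "medication_name")

# Map raw header names to canonical ones; error on missing mandatory columns.
.apply_col_map <- function(raw, mandatory, optional, dialect) {
  map <- dialect$col_map
  for (canon in intersect(names(map), names(raw))) {
    # only rename when the mapped source column exists under its raw name
  }
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
  }
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw[intersect(c(mandatory, optional), names(raw))]
}

#' Read a pharmacy dispensing table
#'
#' Reads a delimited text extract of dispensing records — one row per
#' dispensation — validates every row, and returns the accepted rows as a
#' tibble in file order. Rows failing validation (malformed ATC code,
#' unparseable date, unknown gender, non-positive package count, negative
#' DDD total, or a dispense date outside `data_window`) are dropped, and the
#' returned tibble carries a `read_report` attribute listing each rejected
#' row number with its reason. A missing mandatory column is a hard error.
#'
#' @param path Path to the delimited file.
#' @param dialect A [table_dialect()].
#' @param data_window Optional length-2 `Date` vector; rows dispensed outside
#'   it are rejected.
#' @return A tibble of validated dispensing records with attribute
#'   `read_report` (tibble: `row`, `reason`).
#' @seealso [write_dispensing_table()], [read_death_registry()]
#' @export
read_dispensing_table <- function(path, dialect = table_dialect(),
                                  data_window = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  raw <- .apply_col_map(raw, .dispensing_cols, .dispensing_opt, dialect)
  if (nrow(raw) == 0L) {
    out <- .empty_dispensing()
    attr(out, "read_report") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }

  parsed <- tibble::tibble(
    patient_id    = raw$patient_id,
    birth_date    = as.Date(raw$birth_date, format = dialect$date_format),
    gender        = tolower(raw$gender),
    dispense_date = as.Date(raw$dispense_date, format = dialect$date_format),
    atc_code      = toupper(trimws(raw$atc_code)),
    n_packages    = suppressWarnings(as.integer(raw$n_packages)),
    ddd_total     = suppressWarnings(as.numeric(raw$ddd_total))
  )
  parsed$active_ingredient <- if ("active_ingredient" %in% names(raw))
    raw$active_ingredient else NA_character_
  parsed$medication_name <- if ("medication_name" %in% names(raw))
    raw$medication_name else NA_character_

  reason <- rep(NA_character_, nrow(parsed))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(parsed$patient_id) | parsed$patient_id == "", "missing patient_id")
  flag(is.na(parsed$dispense_date), "unparseable dispense_date")
  flag(is.na(parsed$birth_date), "unparseable birth_date")
  flag(!parsed$gender %in% c("male", "female"), "unknown gender")
  flag(!is_valid_atc(parsed$atc_code), "malformed ATC code")
  flag(is.na(parsed$n_packages) | parsed$n_packages < 1L, "n_packages < 1")
  flag(is.na(parsed$ddd_total) | parsed$ddd_total < 0, "negative or missing ddd_total")
  if (!is.null(data_window)) {
    flag(parsed$dispense_date < data_window[1] | parsed$dispense_date > data_window[2],
         "dispense_date outside data window")
  }

  rejected <- which(!is.na(reason))
  report <- tibble::tibble(row = rejected, reason = reason[rejected])
  out <- parsed[is.na(reason), , drop = FALSE]
  attr(out, "read_report") <- report
  out
}

.empty_dispensing <- function() {
  tibble::tibble(
    patient_id = character(), birth_date = as.Date(character()),
    gender = character(), dispense_date = as.Date(character()),
    atc_code = character(), n_packages = integer(), ddd_total = numeric(),
    active_ingredient = character(), medication_name = character()
  )
}

#' Write a dispensing table
#'
#' Inverse of [read_dispensing_table()] for the same dialect: a subsequent
#' read reproduces the records field-for-field.
#'
#' @param records Tibble of dispensing records.
#' @param path Output path.
#' @param dialect A [table_dialect()].
#' @export
write_dispensing_table <- function(records, path, dialect = table_dialect()) {
  out <- records
  out$birth_date <- format(out$birth_date, dialect$date_format)
  out$dispense_date <- format(out$dispense_date, dialect$date_format)
  readr::write_delim(out, path, delim = dialect$delim, na = "")
  invisible(path)
}

#' Read a death registry
#'
#' @param path Path to a delimited file with columns `patient_id`,
#'   `death_date`.
#' @param dialect A [table_dialect()].
#' @return Tibble with one row per deceased patient. Duplicate patient ids
#'   are an error; the registry keys on the patient.
#' @export
read_death_registry <- function(path, dialect = table_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  raw <- .apply_col_map(raw, c("patient_id", "death_date"), character(), dialect)
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    death_date = as.Date(raw$death_date, format = dialect$date_format)
  )
  if (anyDuplicated(out$patient_id)) {
    stop("death registry contains duplicate patient_id(s)", call. = FALSE)
  }
  out
}

#' Write a death registry
#'
#' @inheritParams write_dispensing_table
#' @param deaths Tibble with columns `patient_id`, `death_date`.
#' @export
write_death_registry <- function(deaths, path, dialect = table_dialect()) {
  out <- deaths
  out$death_date <- format(out$death_date, dialect$date_format)
  readr::write_delim(out, path, delim = dialect$delim, na = "")
  invisible(path)
}

#' Days of supply of a dispensation
#'
#' One Defined Daily Dose (DDD) is one day of supply, so the days covered by
#' a dispensation equal its total number of DDD. Administrative extracts
#' usually carry that number directly (`ddd_total`); when they do not, it is
#' reconstructed as total dispensed amount divided by the DDD, i.e.
#' `n_packages * units_per_package * ddd_per_unit`.
#'
#' @param ddd_total Numeric vector of per-row DDD totals (`NA` when absent).
#' @param n_packages Integer vector of dispensed package counts.
#' @param units_per_package Units (e.g. tablets) per package; used only on
#'   the fallback path.
#' @param ddd_per_unit DDD content of one unit; used only on the fallback
#'   path.
#' @return Numeric vector of days of supply. Zero-day supplies are allowed
#'   but flagged with a warning, since they cannot contribute to adherence.
#' @examples
#' days_supplied(28)                                        # 28
#' days_supplied(NA, n_packages = 2, units_per_package = 28,
#'               ddd_per_unit = 0.5)                        # 28
#' @export
days_supplied <- function(ddd_total, n_packages = NULL,
                          units_per_package = NULL, ddd_per_unit = NULL) {
  out <- as.numeric(ddd_total)
  need <- is.na(out)
  if (any(need)) {
    if (is.null(n_packages) || is.null(units_per_package) || is.null(ddd_per_unit)) {
      stop("ddd_total absent and no package content / DDD-per-unit fallback supplied",
           call. = FALSE)
    }
    out[need] <- (n_packages * units_per_package * ddd_per_unit)[need]
  }
  if (any(out < 0, na.rm = TRUE)) stop("negative days of supply", call. = FALSE)
  if (any(out == 0, na.rm = TRUE)) {
    warning("zero-day supply in ", sum(out == 0, na.rm = TRUE),
            " dispensation(s); these contribute nothing to adherence",
            call. = FALSE)
  }
  out
}
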