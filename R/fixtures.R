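#' Deterministic worked-example fixtures
#'
#' Builds small synthetic dispensing streams whose planted marginal counts
#' equal published study margins, so that the pipeline's selection and
#' classification rules can be verified against printed percentages. All
#' fixture patients are constructed (no sampling) and satisfy the inclusion
#' filters by design; the `seed` argument is accepted for interface
#' uniformity but the fixtures are fully deterministic.
#'
#' Registered fixtures:
#' \describe{
#'   \item{`"intensification"`}{289 metformin initiators with exactly two
#'     distinct antidiabetics, planted as 189 add-on, 92 switch and 8
#'     switch-then-discontinue timelines.}
#'   \item{`"table2"`}{1361 metformin monotherapy initiators split
#'     931/289/92/31/18 across the 1/2/3/4/5+ distinct-antidiabetic
#'     subgroups (the 289 two-drug members are the intensification block).}
#'   \item{`"nine_day"`}{`"table2"` plus 103 metformin-index patients whose
#'     second distinct antidiabetic is dispensed 2-9 days after index
#'     (first-line combination initiators), 1464 metformin-index patients
#'     in all.}
#'   \item{`"table1"`}{`"nine_day"` plus 295 non-metformin single-index
#'     initiators and 168 multi-index-drug starters: 1927 patients, 1090
#'     male, 1759 with one index drug.}
#' }
#'
#' @param name One of `"intensification"`, `"table2"`, `"nine_day"`,
#'   `"table1"`.
#' @param seed Ignored (deterministic construction); kept for interface
#'   symmetry with [generate_population()].
#' @return List of tibbles `records`, `deaths` (empty), `labels`.
#' @export
make_study_fixture <- function(name = c("intensification", "table2",
                                        "nine_day", "table1"),
                               seed = 0L) {
  name <- match.arg(name)
  spec <- switch(name,
    intensification = .fx_spec_intensification(offset = 0L),
    table2 = .fx_spec_table2(),
    nine_day = .fx_spec_nine_day(),
    table1 = .fx_spec_table1()
  )
  .fx_build(spec)
}

.FX_GAP <- 35L     # refill gap, days (supply 28 at CMA 0.8)
.FX_SUPPLY <- 28   # DDD (= days of supply) per dispensation
.FX_END <- as.Date("2021-12-31")
.FX_SECOND <- c("A10BK03", "A10BB09", "A10BJ06", "A10BH01")  # SGLT2i, SU, GLP1, DPP4i
.FX_EXTRA <- c("A10BK03", "A10BB09", "A10BH01", "A10BJ06")
.FX_OTHER_INDEX <- c("A10BB09", "A10AB05", "A10BH01", "A10AE04",
                     "A10BX02", "A10BK03", "A10BG03", "A10BJ06")

# spec: tibble(patient_id, gender, age, index_date, role, second_atc, n_extras)
.fx_patient_spec <- function(prefix, n, n_male, role, offset,
                             second_atc = NA_character_, n_extras = 0L) {
  if (n == 0L) return(NULL)
  i <- seq_len(n) + offset
  tibble::tibble(
    patient_id = sprintf("%s%05d", prefix, seq_len(n)),
    gender = rep(c("male", "female"), c(n_male, n - n_male)),
    age = 45L + (i * 13L) %% 40L,
    index_date = as.Date("2019-01-08") + 7L * ((i - 1L) %% 47L),
    role = role,
    second_atc = second_atc,
    n_extras = n_extras
  )
}

.fx_spec_intensification <- function(offset = 931L) {
  dplyr::bind_rows(
    .fx_patient_spec("AO", 189L, 115L, "add_on", offset,
                     second_atc = rep_len(.FX_SECOND, 189L)),
    .fx_patient_spec("SW", 92L, 56L, "switch", offset + 189L,
                     second_atc = rep_len(.FX_SECOND, 92L)),
    .fx_patient_spec("SD", 8L, 5L, "switch_disc", offset + 281L,
                     second_atc = rep_len(c("A10BK03", "A10BK03", "A10BK03",
                                            "A10BK03", "A10BK03", "A10BB09",
                                            "A10BB09", "A10BJ06"), 8L))
  )
}

.fx_spec_table2 <- function() {
  dplyr::bind_rows(
    .fx_patient_spec("MO", 931L, 488L, "mono", 0L),
    .fx_spec_intensification(offset = 931L),
    .fx_patient_spec("A3", 92L, 54L, "add_on", 1220L,
                     second_atc = .FX_EXTRA[1], n_extras = 2L),
    .fx_patient_spec("A4", 31L, 18L, "add_on", 1312L,
                     second_atc = .FX_EXTRA[1], n_extras = 3L),
    .fx_patient_spec("A5", 18L, 10L, "add_on", 1343L,
                     second_atc = .FX_EXTRA[1], n_extras = 4L)
  )
}

.fx_spec_nine_day <- function() {
  dplyr::bind_rows(
    .fx_spec_table2(),
    .fx_patient_spec("CB", 103L, 103L, "combo", 1361L,
                     second_atc = rep_len(.FX_SECOND, 103L))
  )
}

.fx_spec_table1 <- function() {
  dplyr::bind_rows(
    .fx_spec_nine_day(),
    .fx_patient_spec("OX", 295L, 241L, "other_index", 1464L,
                     second_atc = rep_len(.FX_OTHER_INDEX, 295L)),
    .fx_patient_spec("M2", 152L, 0L, "multi_index", 1759L, n_extras = 1L),
    .fx_patient_spec("M3", 13L, 0L, "multi_index", 1911L, n_extras = 2L),
    .fx_patient_spec("M4", 3L, 0L, "multi_index", 1924L, n_extras = 3L)
  )
}

.FX_MULTI <- c("A10AE04", "A10AB05", "A10BH01")  # same-day co-starters

# one refill stream: dates from `from` to `to` every .FX_GAP days
.fx_dates <- function(from, to = .FX_END) {
  if (from > to) return(as.Date(character()))
  seq(from, to, by = .FX_GAP)
}

.fx_build <- function(spec) {
  streams_pid <- list(); streams_atc <- list(); streams_dates <- list()
  k <- 0L
  add <- function(pid, atc, dates) {
    if (!length(dates)) return(invisible())
    k <<- k + 1L
    streams_pid[[k]] <<- pid; streams_atc[[k]] <<- atc
    streams_dates[[k]] <<- dates
    invisible()
  }
  for (i in seq_len(nrow(spec))) {
    pid <- spec$patient_id[i]; idx <- spec$index_date[i]
    role <- spec$role[i]; second <- spec$second_atc[i]
    if (role == "mono") {
      add(pid, ATC_METFORMIN, .fx_dates(idx))
    } else if (role == "add_on") {
      add(pid, ATC_METFORMIN, .fx_dates(idx))
      extras <- if (spec$n_extras[i] > 0L) {
        .FX_EXTRA[seq_len(spec$n_extras[i])]
      } else second
      for (j in seq_along(extras)) {
        add(pid, extras[j], .fx_dates(idx + 180L * j))
      }
    } else if (role == "switch") {
      add(pid, ATC_METFORMIN, .fx_dates(idx, idx + 179L))
      add(pid, second, .fx_dates(idx + 180L))
    } else if (role == "switch_disc") {
      add(pid, ATC_METFORMIN, .fx_dates(idx, as.Date("2020-12-20")))
      add(pid, second, as.Date(c("2021-01-15", "2021-02-19")))
    } else if (role == "combo") {
      add(pid, ATC_METFORMIN, .fx_dates(idx))
      add(pid, second, .fx_dates(idx + 2L + (i %% 8L)))
    } else if (role == "other_index") {
      add(pid, second, .fx_dates(idx))
    } else if (role == "multi_index") {
      add(pid, ATC_METFORMIN, .fx_dates(idx))
      for (code in .FX_MULTI[seq_len(spec$n_extras[i])]) {
        add(pid, code, .fx_dates(idx))
      }
    } else stop("unknown fixture role: ", role)
  }
  lens <- lengths(streams_dates)
  records <- tibble::tibble(
    patient_id = rep(unlist(streams_pid), lens),
    dispense_date = as.Date(unlist(streams_dates), origin = "1970-01-01"),
    atc_code = rep(unlist(streams_atc), lens),
    n_packages = 1L,
    ddd_total = .FX_SUPPLY
  )
  m <- match(records$patient_id, spec$patient_id)
  records$birth_date <- as.Date(sprintf("%d-06-15", 2021L - spec$age))[m]
  records$gender <- spec$gender[m]
  records$active_ingredient <- NA_character_
  records$medication_name <- NA_character_
  records <- records[order(records$patient_id, records$dispense_date,
                           records$atc_code),
                     c("patient_id", "birth_date", "gender", "dispense_date",
                       "atc_code", "n_packages", "ddd_total",
                       "active_ingredient", "medication_name")]
  archetype <- c(mono = "naive_monotherapy", add_on = "naive_add_on",
                 switch = "naive_switch", switch_disc = "naive_switch_discontinue",
                 combo = "naive_combination", other_index = "naive_monotherapy",
                 multi_index = "naive_combination")[spec$role]
  labels <- tibble::tibble(
    patient_id = spec$patient_id,
    archetype = unname(archetype),
    planted_index_date = spec$index_date,
    planted_second_ad = dplyr::if_else(spec$role %in% c("mono", "other_index"),
                                       NA_character_, spec$second_atc)
  )
  list(records = tibble::as_tibble(records),
       deaths = tibble::tibble(patient_id = character(),
                               death_date = as.Date(character())),
       labels = labels)
}
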