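# Default index-drug mix for synthetic naive initiators: one representative
# ATC-5 code per class, weighted by the observed index-drug distribution
# (percent of single-index-drug initiators).
default_ad_class_weights <- c(
  "A10BA02" = 83.2,  # metformin
  "A10BB09" = 4.7,   # gliclazide (sulfonylureas)
  "A10AB05" = 4.2,   # insulin aspart (fast-acting)
  "A10BH01" = 1.7,   # sitagliptin (DPP-4i)
  "A10AE04" = 1.5,   # insulin glargine (long-acting)
  "A10BX02" = 1.3,   # repaglinide
  "A10BK03" = 1.2,   # empagliflozin (SGLT-2i)
  "A10BG03" = 0.9,   # pioglitazone
  "A10BF01" = 0.9,   # acarbose
  "A10BJ06" = 0.4    # semaglutide (GLP-1RA)
)

.archetypes <- c("prevalent_user", "naive_monotherapy", "naive_combination",
                 "naive_add_on", "naive_switch", "naive_switch_discontinue",
                 "sporadic_user", "decedent")

#' Synthetic-population generator configuration
#'
#' Describes a synthetic administrative dispensing stream: how many
#' patients, over which window, in what mixture of behavioural archetypes,
#' how adherent each archetype is, and with which comorbidity
#' co-dispensation prevalences. Adherence behaviour is modelled through
#' refill gaps — the observable quantity in dispensing data — with the gap
#' between consecutive dispensations set to `days supplied / target CMA`
#' plus optional jitter, so that at `jitter_days = 0` the planted CMA is
#' exact.
#'
#' Default comorbidity prevalences are the monotherapy-subgroup column of
#' the packaged Rx-Risk prevalence profile; default index-drug weights are
#' the observed single-index-drug distribution.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_patients Number of patients.
#' @param date_window Length-2 `Date`, spanning at least two calendar years.
#' @param archetype_mix Named proportions over the eight archetypes
#'   (`prevalent_user`, `naive_monotherapy`, `naive_combination`,
#'   `naive_add_on`, `naive_switch`, `naive_switch_discontinue`,
#'   `sporadic_user`, `decedent`); must sum to 1.
#' @param target_cma Named per-archetype CMA targets in (0, 1.5].
#' @param comorbidity_prevalence Named probability per Rx-Risk condition of
#'   one co-dispensation in that condition's drug classes.
#' @param ad_class_weights Named weights over index-drug ATC-5 codes.
#' @param supply_ddd DDD (= days of supply) per dispensation, default 28.
#' @param jitter_days Uniform refill-gap jitter in days (default 3; use 0
#'   for exact planted CMA).
#' @param prop_male Proportion of male patients.
#' @return A list of class `"rx_generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_patients = 1000L,
                             date_window = as.Date(c("2018-01-01", "2021-12-31")),
                             archetype_mix = c(
                               prevalent_user = 0.55,
                               naive_monotherapy = 0.18,
                               naive_combination = 0.015,
                               naive_add_on = 0.05,
                               naive_switch = 0.025,
                               naive_switch_discontinue = 0.005,
                               sporadic_user = 0.10,
                               decedent = 0.075),
                             target_cma = c(
                               prevalent_user = 0.6,
                               naive_monotherapy = 0.8,
                               naive_combination = 0.6,
                               naive_add_on = 0.6,
                               naive_switch = 0.6,
                               naive_switch_discontinue = 0.6,
                               sporadic_user = 0.6,
                               decedent = 0.6),
                             comorbidity_prevalence = default_comorbidity_prevalence(),
                             ad_class_weights = default_ad_class_weights,
                             supply_ddd = 28,
                             jitter_days = 3L,
                             prop_male = 0.55) {
  stopifnot(n_patients >= 0, supply_ddd > 0, jitter_days >= 0)
  if (!setequal(names(archetype_mix), .archetypes)) {
    stop("archetype_mix must name exactly the eight archetypes", call. = FALSE)
  }
  if (abs(sum(archetype_mix) - 1) > 1e-9) {
    stop("archetype proportions must sum to 1", call. = FALSE)
  }
  if (any(target_cma <= 0) || any(target_cma > 1.5)) {
    stop("target_cma must lie in (0, 1.5]", call. = FALSE)
  }
  if (any(comorbidity_prevalence < 0 | comorbidity_prevalence > 1)) {
    stop("comorbidity prevalences must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(date_window, "Date"), length(date_window) == 2L)
  if (.year_of(date_window[2]) - .year_of(date_window[1]) < 1L) {
    stop("date_window must span at least two calendar years", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 date_window = date_window, archetype_mix = archetype_mix,
                 target_cma = target_cma,
                 comorbidity_prevalence = comorbidity_prevalence,
                 ad_class_weights = ad_class_weights,
                 supply_ddd = supply_ddd, jitter_days = as.integer(jitter_days),
                 prop_male = prop_male),
            class = "rx_generator_config")
}

#' Default comorbidity co-dispensation prevalences
#'
#' One probability per Rx-Risk condition, the monotherapy-subgroup
#' prevalence profile of the packaged map.
#'
#' @return Named numeric vector in [0, 1].
#' @export
default_comorbidity_prevalence <- function() {
  c("Cardiovascular/cerebrovascular diseases and heart diseases" = 1.00,
    "Hypertension" = 1.00,
    "Hyperlipidemia" = 0.625,
    "Hyperuricemia/Gout" = 0.18,
    "Infectious diseases" = 0.838,
    "Acid related disorders" = 0.571,
    "Inflammatory/Rheumatic disorders" = 0.566,
    "Corticosteroid-responsive diseases" = 0.407,
    "Nutrition-related diseases" = 0.365,
    "Pain, including migraine" = 0.299,
    "Depression and other mental disorders" = 0.214,
    "Chronic obstructive airways diseases" = 0.199,
    "Gastrointestinal disorders and nausea" = 0.199,
    "Anemia" = 0.177,
    "Diseases of the genito-urinary system, including benign prostatic hypertrophy" = 0.174,
    "Thyroid disorders" = 0.125,
    "Respiratory diseases" = 0.102,
    "Epilepsy" = 0.097,
    "Dermatological diseases, including psoriasis" = 0.073,
    "Eye disorders, including glaucoma" = 0.071,
    "Psychotic illnesses" = 0.033)
}

# refill dates start, start+gap1, ... <= end, gaps jittered around `gap`
.refill_dates <- function(start, end, gap, jitter) {
  if (start > end) return(as.Date(character()))
  dates <- start
  cur <- start
  repeat {
    g <- gap + if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L else 0L
    cur <- cur + max(1L, g)
    if (cur > end) break
    dates <- c(dates, cur)
  }
  dates
}

# a supply stream: one drug, a vector of dispensation dates
.ad_rows <- function(pid, dates, atc, supply) {
  if (!length(dates)) return(NULL)
  list(pid = pid, dates = dates, atc = atc, ddd = supply)
}

#' Generate a synthetic dispensing stream
#'
#' Produces a dispensing table, a death registry and the planted
#' ground-truth archetype labels for a synthetic population. Deterministic
#' for a fixed seed: one pseudo-random stream seeded at entry, patients
#' emitted in generation order.
#'
#' Archetypes: `prevalent_user` has antidiabetic dispensations already in
#' the wash-out year; `naive_*` archetypes start their first antidiabetic
#' in the index year (`naive_combination` adds a second distinct drug 2-9
#' days after index; `naive_add_on` adds one later with metformin
#' continuing; `naive_switch` replaces metformin;
#' `naive_switch_discontinue` switches and then stops dispensing);
#' `sporadic_user` has a single index-year dispensation and fails the
#' chronic-use filter; `decedent` appears in the death registry. Comorbidity
#' co-dispensations are drawn per condition as independent Bernoulli events
#' at the configured prevalence.
#'
#' @param config A [generator_config()].
#' @return List of tibbles: `records` (dispensing table, including
#'   demographic columns), `deaths`, `labels` (`patient_id`, `archetype`,
#'   `planted_index_date`, `planted_second_ad`).
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "rx_generator_config"))
  n <- config$n_patients
  if (n == 0L) {
    return(list(records = .empty_dispensing(),
                deaths = tibble::tibble(patient_id = character(),
                                        death_date = as.Date(character())),
                labels = tibble::tibble(patient_id = character(),
                                        archetype = character(),
                                        planted_index_date = as.Date(character()),
                                        planted_second_ad = character())))
  }
  set.seed(config$seed)
  win <- config$date_window
  study_end <- win[2]
  index_year <- .year_of(win[1]) + 1L
  index_start <- as.Date(paste0(index_year, "-01-01"))
  index_end <- as.Date(paste0(index_year, "-12-31"))
  supply <- config$supply_ddd
  jit <- config$jitter_days
  map <- rx_risk_map()
  cond_codes <- split(map$atcl2, map$condition)

  # largest-remainder allocation of archetype counts, then shuffled order
  raw <- config$archetype_mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  archetype <- sample(rep(names(counts), counts))

  pid <- sprintf("P%06d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  age <- sample(40:85, n, replace = TRUE)
  birth_date <- as.Date(sprintf("%d-06-15", 2021L - age))
  nonmet <- setdiff(names(config$ad_class_weights), ATC_METFORMIN)
  nonmet_w <- config$ad_class_weights[nonmet]
  second_pool <- c("A10BK03", "A10BB09", "A10BJ06", "A10BH01")

  streams <- vector("list", 4L * n)
  n_streams <- 0L
  push <- function(s) {
    if (is.null(s)) return(invisible())
    n_streams <<- n_streams + 1L
    streams[[n_streams]] <<- s
    invisible()
  }
  deaths <- vector("list", n)
  labels_arch <- character(n)
  labels_index <- rep(as.Date(NA), n)
  labels_second <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    arch <- archetype[i]
    cma <- config$target_cma[[arch]]
    gap <- max(1L, as.integer(round(supply / cma)))
    index_date <- index_start + sample.int(as.integer(index_end - index_start) + 1L, 1L) - 1L
    second <- NA_character_
    death <- as.Date(NA)
    rows <- switch(
      arch,
      prevalent_user = {
        start <- win[1] + sample.int(300L, 1L) - 1L
        drug <- sample(names(config$ad_class_weights), 1L,
                       prob = config$ad_class_weights)
        index_date <- as.Date(NA)
        list(.ad_rows(pid[i], .refill_dates(start, study_end, gap, jit),
                      drug, supply))
      },
      naive_monotherapy = {
        drug <- sample(names(config$ad_class_weights), 1L,
                       prob = config$ad_class_weights)
        list(.ad_rows(pid[i], .refill_dates(index_date, study_end, gap, jit),
                      drug, supply))
      },
      naive_combination = {
        second <- sample(second_pool, 1L)
        d2 <- index_date + sample(2:9, 1L)
        list(.ad_rows(pid[i], .refill_dates(index_date, study_end, gap, jit),
                       ATC_METFORMIN, supply),
              .ad_rows(pid[i], .refill_dates(d2, study_end, gap, jit),
                       second, supply))
      },
      naive_add_on = {
        second <- sample(second_pool, 1L)
        change <- index_date + 60L + sample.int(340L, 1L)
        list(.ad_rows(pid[i], .refill_dates(index_date, study_end, gap, jit),
                      ATC_METFORMIN, supply),
             .ad_rows(pid[i], .refill_dates(change, study_end, gap, jit),
                      second, supply))
      },
      naive_switch = {
        second <- sample(second_pool, 1L)
        change <- index_date + 60L + sample.int(340L, 1L)
        list(.ad_rows(pid[i], .refill_dates(index_date, change - 1L, gap, jit),
                      ATC_METFORMIN, supply),
             .ad_rows(pid[i], .refill_dates(change, study_end, gap, jit),
                      second, supply))
      },
      naive_switch_discontinue = {
        second <- sample(second_pool, 1L)
        change <- as.Date(paste0(index_year + 2L, "-01-15")) + sample.int(20L, 1L)
        list(.ad_rows(pid[i], .refill_dates(index_date,
                                            as.Date(paste0(index_year + 1L, "-12-20")),
                                            gap, jit),
                      ATC_METFORMIN, supply),
             .ad_rows(pid[i], c(change, change + gap), second, supply))
      },
      sporadic_user = {
        drug <- sample(names(config$ad_class_weights), 1L,
                       prob = config$ad_class_weights)
        list(.ad_rows(pid[i], index_date, drug, supply))
      },
      decedent = {
        drug <- sample(names(config$ad_class_weights), 1L,
                       prob = config$ad_class_weights)
        death <- as.Date(paste0(index_year + 2L, "-06-01")) +
          sample.int(as.integer(study_end - as.Date(paste0(index_year + 2L, "-06-01"))), 1L)
        list(.ad_rows(pid[i], .refill_dates(index_date, death, gap, jit),
                      drug, supply))
      },
      stop("unknown archetype: ", arch)
    )
    for (s in rows) push(s)
    # comorbidity co-dispensations, one Bernoulli draw per condition
    drawn <- names(config$comorbidity_prevalence)[
      stats::runif(length(config$comorbidity_prevalence)) <
        config$comorbidity_prevalence]
    if (length(drawn)) {
      codes <- vapply(drawn, function(cn) {
        cands <- cond_codes[[cn]]
        paste0(cands[sample.int(length(cands), 1L)], "AA01")
      }, character(1), USE.NAMES = FALSE)
      dates <- win[1] + sample.int(as.integer(study_end - win[1]) + 1L,
                                   length(codes), replace = TRUE) - 1L
      push(list(pid = pid[i], dates = dates, atc = codes, ddd = 30))
    }
    if (!is.na(death)) {
      deaths[[i]] <- tibble::tibble(patient_id = pid[i], death_date = death)
    }
    labels_arch[i] <- arch
    labels_index[i] <- index_date
    labels_second[i] <- second
  }

  streams <- streams[seq_len(n_streams)]
  lens <- vapply(streams, function(s) length(s$dates), integer(1))
  rec <- tibble::tibble(
    patient_id = rep(vapply(streams, `[[`, character(1), "pid"), lens),
    dispense_date = as.Date(unlist(lapply(streams, `[[`, "dates")),
                            origin = "1970-01-01"),
    atc_code = unlist(lapply(streams, function(s) rep_len(s$atc, length(s$dates)))),
    n_packages = 1L,
    ddd_total = rep(vapply(streams, `[[`, numeric(1), "ddd"), lens))
  rec$birth_date <- birth_date[match(rec$patient_id, pid)]
  rec$gender <- gender[match(rec$patient_id, pid)]
  rec$active_ingredient <- NA_character_
  rec$medication_name <- NA_character_
  rec <- rec[order(rec$patient_id, rec$dispense_date, rec$atc_code),
             c("patient_id", "birth_date", "gender", "dispense_date",
               "atc_code", "n_packages", "ddd_total", "active_ingredient",
               "medication_name")]
  list(records = tibble::as_tibble(rec),
       deaths = dplyr::bind_rows(deaths) %||%
         tibble::tibble(patient_id = character(), death_date = as.Date(character())),
       labels = tibble::tibble(patient_id = pid, archetype = labels_arch,
                               planted_index_date = labels_index,
                               planted_second_ad = labels_second))
}

`%||%` <- function(x, y) if (is.null(x) || (is.data.frame(x) && !nrow(x))) y else x
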