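#' Median and interquartile range
#'
#' Order-statistic median with quartiles by linear interpolation between
#' order statistics ([stats::quantile()] type 7), the convention used
#' throughout the package's summary tables.
#'
#' @param values Non-empty numeric vector.
#' @return A list: `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # median 2.5
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("empty value list", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction on an r x c count
#' table; degrees of freedom (r-1)(c-1). A zero row or column margin is an
#' error naming the degenerate margin, not a silent NaN.
#'
#' @param table Numeric matrix of non-negative counts, at least 2x2.
#' @return A list: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(rbind(c(10, 20), c(20, 10)))
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L, all(table >= 0))
  if (any(rowSums(table) == 0)) {
    stop("zero row margin at row ", which(rowSums(table) == 0)[1], call. = FALSE)
  }
  if (any(colSums(table) == 0)) {
    stop("zero column margin at column ", which(colSums(table) == 0)[1],
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition across k groups.
#' When every value is identical the F statistic is 0 by convention, with a
#' warning.
#'
#' @param groups List of numeric vectors, one per group; at least two
#'   groups, at least one with two or more values.
#' @return A list: `statistic` (F), `df` (length-2: between, within),
#'   `p_value`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6))) # F = 13.5
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("at least two groups required", call. = FALSE)
  if (any(lengths(groups) < 1L)) stop("empty group", call. = FALSE)
  if (!any(lengths(groups) >= 2L)) {
    stop("at least one group needs two or more values", call. = FALSE)
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df <- c(nlevels(g) - 1L, length(y) - nlevels(g))
  if (stats::var(y) == 0) {
    warning("all values identical; F = 0 by convention", call. = FALSE)
    return(list(statistic = 0, df = df, p_value = 1))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  list(statistic = fit$`F value`[1], df = df, p_value = fit$`Pr(>F)`[1])
}

# "<0.01" rendering used in printed tables; raw p retained in machine output.
.format_p <- function(p) ifelse(p < 0.01, "<0.01", formatC(p, digits = 2, format = "f"))

#' Assemble the full descriptive report
#'
#' Runs the descriptive summaries over the pipeline's outputs: index-drug
#' distribution, subgroup characteristics with a chi-square test on gender
#' and a one-way ANOVA on age, ATC level-1 usage, Rx-Risk prevalence,
#' first-intensification frequencies and the adherence summary. Percentages
#' are rounded half-up to one decimal. Orphan patient ids across inputs are
#' an error.
#'
#' @param cohort Full naive cohort tibble (from [select_naive_cohort()]).
#' @param metformin_cohort Metformin cohort tibble (or `NULL` to skip the
#'   subgroup panels).
#' @param records Dispensing records.
#' @param trajectories Tibble from [classify_trajectories()], or `NULL`.
#' @param adherence Tibble from [cohort_adherence()], or `NULL`.
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; each table is also written as CSV.
#' @return Named list of tibbles.
#' @export
render_report <- function(cohort, metformin_cohort = NULL, records,
                          trajectories = NULL, adherence = NULL,
                          cfg = study_config(), out_dir = NULL) {
  if (nrow(cohort) == 0L) {
    warning("empty cohort; empty report", call. = FALSE)
    return(list())
  }
  for (nm in c("trajectories", "adherence")) {
    x <- get(nm)
    if (!is.null(x) && length(orphans <- setdiff(x$patient_id, cohort$patient_id))) {
      stop("orphan patient_id(s) in ", nm, ": ",
           paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(cohort)
  age <- .age_completed_years(cohort$birth_date, cfg$age_reference_date)

  population <- tibble::tibble(
    label = c("Study population, N", "Males, N", "Males, %",
              "Age, median", "Age, q1", "Age, q3"),
    value = c(n, sum(cohort$gender == "male"),
              .round_half_up(mean(cohort$gender == "male") * 100, 1),
              unlist(median_iqr(age), use.names = FALSE))
  )

  index_drug_counts <- cohort |>
    dplyr::count(n_index_drugs = pmin(.data$n_index_drugs, 4L)) |>
    dplyr::mutate(label = ifelse(.data$n_index_drugs >= 4, "4+",
                                 as.character(.data$n_index_drugs)),
                  percent = .round_half_up(.data$n / !!n * 100, 1)) |>
    dplyr::select("label", "n", "percent")

  single <- cohort[cohort$n_index_drugs == 1L, , drop = FALSE]
  index_drug_distribution <- tibble::tibble(
    atc_code = unlist(single$index_drugs)) |>
    dplyr::count(.data$atc_code) |>
    dplyr::mutate(percent = .round_half_up(.data$n / nrow(single) * 100, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))

  out <- list(population = population,
              index_drug_counts = index_drug_counts,
              index_drug_distribution = index_drug_distribution)

  if (!is.null(metformin_cohort) && nrow(metformin_cohort)) {
    mc <- metformin_cohort
    mc$age <- .age_completed_years(mc$birth_date, cfg$age_reference_date)
    sizes <- dplyr::count(mc, .data$subgroup)
    sizes$percent <- .round_half_up(sizes$n / nrow(mc) * 100, 1)
    gender_tab <- table(mc$gender, mc$subgroup)
    chi <- if (all(dim(gender_tab) >= 2)) chi_square_independence(gender_tab) else NULL
    aov_res <- if (nrow(sizes) >= 2) one_way_anova(split(mc$age, mc$subgroup)) else NULL
    characteristics <- mc |>
      dplyr::group_by(.data$subgroup) |>
      dplyr::summarise(
        n = dplyr::n(),
        males_n = sum(.data$gender == "male"),
        males_percent = .round_half_up(mean(.data$gender == "male") * 100, 1),
        age_median = stats::median(.data$age),
        age_q1 = stats::quantile(.data$age, 0.25, names = FALSE, type = 7),
        age_q3 = stats::quantile(.data$age, 0.75, names = FALSE, type = 7),
        .groups = "drop")
    out$subgroup_sizes <- sizes
    out$subgroup_characteristics <- characteristics
    out$tests <- tibble::tibble(
      test = c("gender x subgroup chi-square", "age x subgroup one-way ANOVA"),
      statistic = c(if (is.null(chi)) NA_real_ else chi$statistic,
                    if (is.null(aov_res)) NA_real_ else aov_res$statistic),
      p_value = c(if (is.null(chi)) NA_real_ else chi$p_value,
                  if (is.null(aov_res)) NA_real_ else aov_res$p_value),
      p_printed = .format_p(p_value))
    out$atcl1_usage <- atcl1_usage_table(mc, records)
    out$comorbidity_prevalence <- prevalence_table(
      assign_comorbidities(records[records$patient_id %in% mc$patient_id, ,
                                   drop = FALSE]),
      mc)
  }
  if (!is.null(trajectories)) {
    out$intensification <- intensification_summary(trajectories)
  }
  if (!is.null(adherence)) {
    out$adherence <- adherence_table(adherence)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- out
    flat$intensification <- NULL; flat$adherence <- NULL
    if (!is.null(out$intensification)) {
      flat$intensification_by_category <- out$intensification$by_category
      flat$intensification_by_class <- out$intensification$by_class
    }
    if (!is.null(out$adherence)) {
      flat$adherence_by_subgroup <- out$adherence$by_subgroup
      flat$adherence_strata <- out$adherence$strata
      flat$adherence_cross_subgroup <- out$adherence$cross_subgroup
    }
    for (nm in names(flat)) {
      readr::write_csv(flat[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  out
}
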