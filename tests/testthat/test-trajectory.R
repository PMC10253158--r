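cfg <- study_config()

met_until <- function(id, to) refill_records(id, "2019-03-15", to, 35)

test_that("add-on, switch and switch-then-discontinue timelines classify correctly", {
  idx <- as.Date("2019-03-15")
  # metformin continues after gliclazide starts: add-on
  addon <- dplyr::bind_rows(
    met_until("P1", "2021-12-01"),
    refill_records("P1", "2019-09-15", "2021-12-01", 35, atc = "A10BB09"))
  lab <- classify_first_intensification(addon, idx, cfg)
  expect_equal(lab$category, "add_on")
  expect_equal(lab$change_date, as.Date("2019-09-15"))
  expect_equal(intensification_class(lab$change_atc), "sulfonylureas")

  # metformin stops, dapagliflozin refills continue to study end: switch
  switch_tl <- dplyr::bind_rows(
    met_until("P2", "2019-08-01"),
    refill_records("P2", "2019-09-15", "2021-12-15", 35, atc = "A10BK01"))
  lab2 <- classify_first_intensification(switch_tl, idx, cfg)
  expect_equal(lab2$category, "switch")
  expect_equal(intensification_class(lab2$change_atc), "SGLT-2 inhibitors")

  # one SGLT-2i dispensation then nothing: switch then discontinue
  disc <- dplyr::bind_rows(
    met_until("P3", "2019-08-01"),
    make_records("P3", "2019-09-15", "A10BK01"))
  expect_equal(classify_first_intensification(disc, idx, cfg)$category,
               "switch_then_discontinue")

  # no second drug at all: monotherapy
  lab4 <- classify_first_intensification(met_until("P4", "2021-12-01"), idx, cfg)
  expect_equal(lab4$category, "monotherapy")
  expect_true(is.na(lab4$change_date))

  expect_error(classify_first_intensification(
    make_records("P5", "2019-03-15", "C07AB03"), idx, cfg), "empty")
})

test_that("a metformin-containing fixed-dose combination is an add-on even without plain metformin", {
  idx <- as.Date("2019-03-15")
  fdc <- dplyr::bind_rows(
    met_until("P1", "2019-08-01"),
    refill_records("P1", "2019-09-15", "2021-12-01", 35, atc = "A10BD07"))
  lab <- classify_first_intensification(fdc, idx, cfg)
  expect_equal(lab$category, "add_on")
  expect_equal(intensification_class(lab$change_atc),
               "fixed-dose combinations (metformin/sitagliptin)")
})

test_that("a second drug inside the 9-day window is not a therapy change", {
  idx <- as.Date("2019-03-15")
  tl <- dplyr::bind_rows(
    met_until("P1", "2021-12-01"),
    make_records("P1", "2019-03-20", "A10BK01"))
  expect_equal(classify_first_intensification(tl, idx, cfg)$category,
               "monotherapy")
})

test_that("reporting classes map level-4 groups, combinations and insulins", {
  expect_equal(intensification_class(c("A10BB09", "A10BH01", "A10BJ06", "A10BK03")),
               c("sulfonylureas", "DPP-4 inhibitors", "GLP-1 receptor agonists",
                 "SGLT-2 inhibitors"))
  expect_equal(intensification_class("A10AB05"), "insulins alone or in combination")
  expect_equal(intensification_class("A10AE04"), "insulins alone or in combination")
  expect_error(intensification_class("C07AB03"), "non-antidiabetic")
})

test_that("labels are invariant to duplicate same-day dispensations", {
  idx <- as.Date("2019-03-15")
  tl <- dplyr::bind_rows(
    met_until("P1", "2021-12-01"),
    refill_records("P1", "2019-09-15", "2021-12-01", 35, atc = "A10BB09"))
  dup <- dplyr::bind_rows(tl, tl[tl$atc_code == "A10BB09", ][1, ])
  expect_equal(classify_first_intensification(dup, idx, cfg),
               classify_first_intensification(tl, idx, cfg))
})

test_that("intensification summaries partition the two-drug subgroup", {
  fx <- make_study_fixture("intensification")
  sel <- select_naive_cohort(fx$records, fx$deaths, cfg)
  ref <- refine_metformin_cohort(sel$cohort, fx$records, cfg)
  tr <- classify_trajectories(ref$metformin_cohort, fx$records, cfg)
  s <- intensification_summary(tr)
  expect_equal(sum(s$by_category$n), nrow(ref$metformin_cohort))
  expect_setequal(s$by_category$category,
                  c("add_on", "switch", "switch_then_discontinue"))
  # every member gets exactly one category
  expect_equal(nrow(tr), dplyr::n_distinct(tr$patient_id))
  # all-monotherapy input warns and returns empty
  mono <- tibble::tibble(patient_id = "P1", category = "monotherapy",
                         change_date = as.Date(NA), change_atc = NA_character_,
                         reporting_class = NA_character_, subgroup = "2")
  expect_warning(s2 <- intensification_summary(mono), "no intensification")
  expect_equal(nrow(s2$by_category), 0)
})
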