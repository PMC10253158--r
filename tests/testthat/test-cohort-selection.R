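cfg <- study_config()

test_that("exclusion reasons follow the selection order, first failure wins", {
  recs <- dplyr::bind_rows(
    # prevalent user: antidiabetic already in the wash-out year
    refill_records("PREV", "2018-06-01", "2021-12-01", 35),
    # sporadic user: one dispensation in the index year, nothing after
    make_records("SPOR", "2019-03-05", "A10BA02"),
    # minor at the reference date, would otherwise qualify
    refill_records("MINOR", "2019-02-01", "2021-12-01", 35,
                   birth_date = as.Date("2010-01-01")),
    # dies during the study, otherwise fully eligible
    refill_records("DEAD", "2019-02-01", "2021-11-01", 35),
    # starts in 2020, not in the index year
    refill_records("LATE", "2020-02-01", "2021-12-01", 35),
    # fully eligible naive initiator
    refill_records("OK", "2019-03-15", "2021-12-01", 35)
  )
  deaths <- tibble::tibble(patient_id = "DEAD",
                           death_date = as.Date("2021-11-20"))
  res <- select_naive_cohort(recs, deaths, cfg)
  expect_equal(res$cohort$patient_id, "OK")
  led <- tibble::deframe(res$ledger)
  expect_equal(led[["PREV"]], "wash-out")
  expect_equal(led[["SPOR"]], "follow-up frequency")
  expect_equal(led[["MINOR"]], "age")
  expect_equal(led[["DEAD"]], "death")
  expect_equal(led[["LATE"]], "index-year")
  # ledger completeness: every input patient is retained or explained
  expect_equal(nrow(res$cohort) + nrow(res$ledger),
               dplyr::n_distinct(recs$patient_id))
})

test_that("one dispensation in 2019 with none in 2020 fails the chronic-use filter", {
  recs <- make_records("P1", "2019-06-01", "A10BA02")
  res <- select_naive_cohort(recs, NULL, cfg)
  expect_equal(res$ledger$reason, "follow-up frequency")
})

test_that("cohort members are naive and follow-up ends at the last dispensation", {
  recs <- refill_records("P1", "2019-03-15", "2021-10-01", 35)
  res <- select_naive_cohort(recs, NULL, cfg)
  m <- res$cohort
  expect_equal(m$index_date, as.Date("2019-03-15"))
  expect_equal(m$follow_up_end, max(recs$dispense_date))
  expect_true(all(recs$dispense_date >= m$index_date))
  expect_equal(m$subgroup, "1")
})

test_that("index events pick the first index-year dispensation and all same-day drugs", {
  recs <- make_records("P1", c("2019-03-05", "2019-06-01"),
                       c("A10BA02", "A10BB09"))
  ev <- find_index_event(recs, cfg)
  expect_equal(ev$index_date, as.Date("2019-03-05"))
  expect_equal(ev$index_drugs, "A10BA02")

  both <- make_records("P2", c("2019-03-05", "2019-03-05"),
                       c("A10BA02", "A10AE04"))
  expect_length(find_index_event(both, cfg)$index_drugs, 2)

  expect_error(find_index_event(make_records("P3", "2020-01-05", "A10BA02"), cfg),
               "index year")
  expect_error(find_index_event(
    make_records("P4", c("2018-12-05", "2019-02-01"), c("A10BA02", "A10BA02")),
    cfg), "naive")
})

test_that("the 9-day combination window is inclusive of day 9", {
  base <- function(id, second_day) dplyr::bind_rows(
    refill_records(id, "2019-03-15", "2021-12-01", 35),
    refill_records(id, as.Date("2019-03-15") + second_day, "2021-12-01", 35,
                   atc = "A10BK03")
  )
  recs <- dplyr::bind_rows(base("DAY9", 9), base("DAY10", 10))
  sel <- select_naive_cohort(recs, NULL, cfg)
  ref <- refine_metformin_cohort(sel$cohort, recs, cfg)
  expect_equal(ref$combination_initiators$patient_id, "DAY9")
  expect_equal(ref$metformin_cohort$patient_id, "DAY10")
})

test_that("refinement keeps only sole-metformin index patients", {
  recs <- dplyr::bind_rows(
    refill_records("MET", "2019-03-15", "2021-12-01", 35),
    refill_records("SU", "2019-03-15", "2021-12-01", 35, atc = "A10BB09"),
    dplyr::bind_rows(
      refill_records("TWO", "2019-03-15", "2021-12-01", 35),
      refill_records("TWO", "2019-03-15", "2021-12-01", 35, atc = "A10AE04")
    )
  )
  sel <- select_naive_cohort(recs, NULL, cfg)
  ref <- refine_metformin_cohort(sel$cohort, recs, cfg)
  expect_equal(ref$metformin_cohort$patient_id, "MET")
  expect_equal(nrow(ref$combination_initiators), 0)
})

test_that("distinct-antidiabetic subgroups bucket at five or more", {
  expect_equal(ad_subgroup(c(1, 2, 4, 5, 6)), c("1", "2", "4", "5+", "5+"))
  expect_error(ad_subgroup(0))
})

test_that("selection is order-independent and idempotent", {
  g <- generate_population(generator_config(seed = 42, n_patients = 300))
  res <- select_naive_cohort(g$records, g$deaths, cfg)
  shuffled <- g$records[sample.int(nrow(g$records)), , drop = FALSE]
  res2 <- select_naive_cohort(shuffled, g$deaths, cfg)
  expect_equal(res2$cohort, res$cohort)
  # idempotence: re-selecting from the cohort's own records changes nothing
  sub <- g$records[g$records$patient_id %in% res$cohort$patient_id, , drop = FALSE]
  res3 <- select_naive_cohort(sub, g$deaths, cfg)
  expect_equal(res3$cohort, res$cohort)
  expect_equal(nrow(res3$ledger), 0)
})

test_that("empty input yields an empty cohort and ledger", {
  res <- select_naive_cohort(make_records(character(), character(), character()),
                             NULL, cfg)
  expect_equal(nrow(res$cohort), 0)
  expect_equal(nrow(res$ledger), 0)
})
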