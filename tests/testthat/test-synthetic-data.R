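test_that("generation is deterministic per seed and honours n = 0", {
  cfg <- generator_config(seed = 5, n_patients = 120)
  g1 <- generate_population(cfg)
  g2 <- generate_population(cfg)
  expect_identical(g1, g2)
  g3 <- generate_population(generator_config(seed = 6, n_patients = 120))
  expect_false(identical(g1$records, g3$records))

  empty <- generate_population(generator_config(n_patients = 0))
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$deaths), 0)
  expect_equal(nrow(empty$labels), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(target_cma = c(
    prevalent_user = 0, naive_monotherapy = 0.8, naive_combination = 0.6,
    naive_add_on = 0.6, naive_switch = 0.6, naive_switch_discontinue = 0.6,
    sporadic_user = 0.6, decedent = 0.6)), "target_cma")
  expect_error(generator_config(archetype_mix = c(
    prevalent_user = 0.9, naive_monotherapy = 0.2, naive_combination = 0,
    naive_add_on = 0, naive_switch = 0, naive_switch_discontinue = 0,
    sporadic_user = 0, decedent = 0)), "sum to 1")
  expect_error(generator_config(date_window = as.Date(c("2019-01-01",
                                                        "2019-12-31"))),
               "two calendar years")
})

test_that("planted monotherapy CMA is exact at zero jitter", {
  mix <- c(prevalent_user = 0, naive_monotherapy = 1, naive_combination = 0,
           naive_add_on = 0, naive_switch = 0, naive_switch_discontinue = 0,
           sporadic_user = 0, decedent = 0)
  g <- generate_population(generator_config(seed = 3, n_patients = 100,
                                            jitter_days = 0,
                                            archetype_mix = mix))
  sel <- select_naive_cohort(g$records, g$deaths)
  expect_equal(nrow(sel$cohort), 100)
  adh <- cohort_adherence(sel$cohort, g$records)
  # gap = supply / target CMA = 28 / 0.8 = 35 days: exactly 80% covered
  expect_equal(adh$cma_percent, rep(80, 100))
})

test_that("planted archetypes are recovered by selection and classification", {
  g <- generate_population(generator_config(seed = 17, n_patients = 600,
                                            jitter_days = 0))
  sel <- select_naive_cohort(g$records, g$deaths)
  lab <- g$labels
  included <- lab$patient_id %in% sel$cohort$patient_id
  naive <- startsWith(lab$archetype, "naive")
  expect_true(all(included[naive]))
  expect_false(any(included[!naive]))
  reasons <- tibble::deframe(sel$ledger)
  expect_true(all(reasons[lab$patient_id[lab$archetype == "prevalent_user"]]
                  == "wash-out"))
  expect_true(all(reasons[lab$patient_id[lab$archetype == "sporadic_user"]]
                  == "follow-up frequency"))
  expect_true(all(reasons[lab$patient_id[lab$archetype == "decedent"]]
                  == "death"))

  ref <- refine_metformin_cohort(sel$cohort, g$records)
  expect_setequal(ref$combination_initiators$patient_id,
                  lab$patient_id[lab$archetype == "naive_combination"])
  tr <- classify_trajectories(ref$metformin_cohort, g$records)
  m <- dplyr::inner_join(tr, lab, by = "patient_id")
  expected <- c(naive_monotherapy = "monotherapy", naive_add_on = "add_on",
                naive_switch = "switch",
                naive_switch_discontinue = "switch_then_discontinue")
  expect_equal(m$category, unname(expected[m$archetype]))
})

test_that("empirical comorbidity prevalence tracks the configured probabilities", {
  n <- 1200
  g <- generate_population(generator_config(seed = 23, n_patients = n))
  cm <- assign_comorbidities(g$records)
  p <- default_comorbidity_prevalence()
  for (cond in c("Hyperlipidemia", "Infectious diseases",
                 "Chronic obstructive airways diseases")) {
    obs <- sum(cm$condition == cond) / n
    se <- sqrt(p[[cond]] * (1 - p[[cond]]) / n)
    expect_lt(abs(obs - p[[cond]]), 3 * se + 1e-12)
  }
  # certain conditions are flagged for everyone
  expect_equal(sum(cm$condition == "Hypertension"), n)
})

test_that("fixtures reproduce their planted marginal counts", {
  fx <- make_study_fixture("intensification")
  expect_equal(nrow(fx$labels), 289)
  counts <- table(fx$labels$archetype)
  expect_equal(as.integer(counts[c("naive_add_on", "naive_switch",
                                   "naive_switch_discontinue")]),
               c(189L, 92L, 8L))

  t1 <- make_study_fixture("table1")
  expect_equal(nrow(t1$labels), 1927)
  expect_equal(sum(dplyr::distinct(t1$records, patient_id,
                                   gender)$gender == "male"), 1090)

  nd <- make_study_fixture("nine_day")
  expect_equal(nrow(nd$labels), 1464)
  expect_equal(sum(nd$labels$archetype == "naive_combination"), 103)

  expect_error(make_study_fixture("not_a_fixture"))
})
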