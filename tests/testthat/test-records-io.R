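test_that("ATC prefixes follow the 1/3/4/5/7 level structure", {
  expect_equal(atc_prefix("A10BA02", 1), "A")
  expect_equal(atc_prefix("A10BA02", 2), "A10")
  expect_equal(atc_prefix("C09AA05", 4), "C09AA")
  expect_equal(atc_prefix("C09AA05", 5), "C09AA05")
  expect_error(atc_prefix("A10BA02", 6), "level")
  expect_error(atc_prefix("10ABA", 2), "malformed")
  # idempotent under re-prefixing
  codes <- c("A10BA02", "C09AA05", "J01CA04", "N02BE01")
  expect_equal(atc_prefix(atc_prefix(codes, 5), 2), atc_prefix(codes, 2))
  expect_equal(atc_prefix(atc_prefix(codes, 3), 2), atc_prefix(codes, 2))
})

test_that("antidiabetics are exactly the A10 group", {
  expect_true(is_antidiabetic("A10BA02"))
  expect_true(is_antidiabetic("A10BD07"))  # fixed-dose combination
  expect_true(is_antidiabetic("A10AB05"))  # insulin
  expect_false(is_antidiabetic("C10AA01"))
  expect_false(is_antidiabetic("A02BC01"))
  expect_error(is_antidiabetic("A1"), "malformed")
})

test_that("metformin fixed-dose combinations are recognised by component", {
  expect_true(all(is_metformin_fdc(c("A10BD02", "A10BD07", "A10BD15", "A10BD20"))))
  expect_false(any(is_metformin_fdc(c("A10BD04", "A10BD19", "A10BD21"))))
  expect_false(is_metformin_fdc("A10BA02"))  # plain metformin is not an FDC
  expect_warning(res <- is_metformin_fdc("A10BD99"), "unknown")
  expect_false(res)
})

test_that("days of supply come from the DDD total with an amount/DDD fallback", {
  expect_equal(days_supplied(28), 28)
  expect_equal(days_supplied(NA, n_packages = 2, units_per_package = 28,
                             ddd_per_unit = 0.5), 28)
  expect_warning(z <- days_supplied(0), "zero-day")
  expect_equal(z, 0)
  expect_error(days_supplied(NA), "fallback")
  expect_error(days_supplied(-1), "negative")
  # additive over packages: n packages = n times one package
  one <- days_supplied(NA, n_packages = 1, units_per_package = 30,
                       ddd_per_unit = 0.5)
  five <- days_supplied(NA, n_packages = 5, units_per_package = 30,
                        ddd_per_unit = 0.5)
  expect_equal(five, 5 * one)
})

test_that("dispensing tables round-trip through write and read", {
  recs <- make_records(
    c("P1", "P1", "P2"),
    c("2019-03-05", "2019-04-02", "2019-06-01"),
    c("A10BA02", "A10BA02", "C07AB03"),
    gender = c("male", "male", "female")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_dispensing_table(recs, path)
  back <- read_dispensing_table(path)
  expect_equal(nrow(attr(back, "read_report")), 0)
  attr(back, "read_report") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("malformed rows are rejected and logged, not fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,birth_date,gender,dispense_date,atc_code,n_packages,ddd_total",
    "P1,1960-06-15,male,2019-03-05,A10BA02,1,28",
    "P2,1960-06-15,male,2019-03-05,10ABA,1,28",
    "P3,1960-06-15,other,2019-03-05,A10BA02,1,28",
    "P4,1960-06-15,female,not-a-date,A10BA02,1,28"
  ), path)
  res <- read_dispensing_table(path)
  expect_equal(nrow(res), 1)
  report <- attr(res, "read_report")
  expect_equal(report$row, c(2L, 3L, 4L))
  expect_match(report$reason[1], "ATC")
  expect_match(report$reason[2], "gender")
  expect_match(report$reason[3], "date")
})

test_that("empty files and dialects with column maps are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,birth_date,gender,dispense_date,atc_code,n_packages,ddd_total",
             path)
  expect_equal(nrow(read_dispensing_table(path)), 0)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdob\tsex\tdate\tatc\tpk\tddd",
               "P1\t15/06/1960\tmale\t05/03/2019\tA10BA02\t1\t28"), path2)
  dia <- table_dialect(delim = "\t", date_format = "%d/%m/%Y",
                       col_map = c(patient_id = "id", birth_date = "dob",
                                   gender = "sex", dispense_date = "date",
                                   atc_code = "atc", n_packages = "pk",
                                   ddd_total = "ddd"))
  res <- read_dispensing_table(path2, dia)
  expect_equal(res$dispense_date, as.Date("2019-03-05"))

  writeLines(c("id,dob", "P1,1960-06-15"), path)
  expect_error(read_dispensing_table(path), "mandatory column")
})

test_that("death registries read, write and reject duplicate patients", {
  deaths <- tibble::tibble(patient_id = c("P1", "P2"),
                           death_date = as.Date(c("2021-05-01", "2020-11-30")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_death_registry(deaths, path)
  expect_equal(as.data.frame(read_death_registry(path)), as.data.frame(deaths))
  writeLines(c("patient_id,death_date", "P1,2021-05-01", "P1,2021-06-01"), path)
  expect_error(read_death_registry(path), "duplicate")
})
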