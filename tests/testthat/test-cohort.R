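# cohort data model, CSV round trip, validation, descriptives

test_that("a valid cohort round-trips through CSV field for field", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture_suite(dir)
  coh <- read_cohort(paths[["clean"]])
  expect_s3_class(coh, "injury_cohort")
  expect_equal(nrow(coh), 10)

  out <- file.path(dir, "rt.csv")
  write_cohort(coh, out)
  coh2 <- read_cohort(out)
  expect_equal(as.data.frame(coh2), as.data.frame(coh))

  # column order and bytes are stable across writes
  out2 <- file.path(dir, "rt2.csv")
  write_cohort(coh, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("missing demographics are excluded and invariant violations rejected with diagnostics", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture_suite(dir)
  expect_warning(coh <- read_cohort(paths[["invalid"]]), "rejected")
  # of 4 rows: one missing sex, one negative workdays, one zero wage
  expect_equal(nrow(coh), 1)
  expect_equal(attr(coh, "excluded_missing_demographics"), 1)
  rej <- attr(coh, "rejected")
  expect_equal(nrow(rej), 2)
  expect_true(any(grepl("workdays_lost < 0", rej$reason)))
  expect_true(any(grepl("daily_wage", rej$reason)))

  # missing-age rule only applies when an age column is present
  df <- make_records(c(3, 7, 9))
  df$age <- c(30, NA, 41)
  coh_a <- as_injury_cohort(df, quiet = TRUE)
  expect_equal(nrow(coh_a), 2)
  expect_equal(attr(coh_a, "excluded_missing_demographics"), 1)
})

test_that("read and construction errors are informative", {
  expect_error(read_cohort(tempfile(fileext = ".csv")), "not found")
  df <- make_records(1:3)
  expect_error(as_injury_cohort(df[, -2], quiet = TRUE), "missing required")
  bad <- df
  bad$workdays_lost <- -1
  expect_error(as_injury_cohort(bad, quiet = TRUE), "empty after validation")
  dup <- df
  dup$worker_id <- "W00001"
  expect_error(as_injury_cohort(dup, quiet = TRUE), "unique")
  expect_error(suppressWarnings(
    write_cohort(make_cohort(1:3),
                 file.path(tempdir(), "no/such/dir/x.csv"))))
})

test_that("workday summary totals, medians and absence bins are correct", {
  s <- summarize_workdays(make_cohort(c(1, 2, 3, 4, 100)))
  expect_equal(s$total_days, 110)
  expect_equal(s$median_days, 3)
  expect_equal(unname(s$counts), c(4, 0, 1))

  z <- summarize_workdays(make_cohort(rep(0, 6)))
  expect_equal(z$total_days, 0)
  expect_equal(z$median_days, 0)

  # published bin structure: 48 / 894 / 258 of 1200 -> 4.0%, 74.5%, 21.5%
  days <- c(rep(2, 48), rep(10, 894), rep(40, 258))
  p <- summarize_workdays(make_cohort(days))$proportions
  expect_equal(round_half_up(100 * unname(p), 1), c(4.0, 74.5, 21.5))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # bin boundaries: 5 and 30 belong to the middle bin, 31 to the upper
  b <- summarize_workdays(make_cohort(c(4, 5, 30, 31)))$counts
  expect_equal(unname(b), c(1, 2, 1))
})

test_that("workday median matches a sort-based oracle on random cohorts", {
  withr::local_seed(11)
  for (i in 1:20) {
    days <- sample(0:120, sample(3:400, 1), replace = TRUE)
    expect_equal(summarize_workdays(make_cohort(days))$median_days,
                 sort_median(days))
  }
})

test_that("category distributions render like published frequency tables", {
  cls <- rep(c("temporary_total", "permanent_partial", "permanent_total",
               "death"), times = c(476, 607, 70, 47))
  coh <- make_cohort(days = rep(1, 1200), disability = cls)
  d <- category_distribution(coh, "disability_class")
  expect_equal(d$count, c(476, 607, 70, 47))
  expect_equal(d$percent, c(39.7, 50.6, 5.8, 3.9))
  expect_lt(abs(sum(d$percent) - 100), 0.2)

  eq <- make_cohort(days = rep(1, 100),
                    disability = rep(cohort_levels$disability_class, 25))
  expect_equal(category_distribution(eq, "disability_class")$percent,
               rep(25.0, 4))

  single <- category_distribution(make_cohort(1:5), "disability_class")
  expect_equal(single$percent[single$level == "temporary_total"], 100)
  expect_error(category_distribution(coh, "shoe_size"), "unknown field")
  expect_error(category_distribution(coh, "daily_wage"), "not categorical")
})

test_that("sample_size implements the single population proportion formula", {
  expect_identical(sample_size(0.5, 0.05, 1.96, 1.0), 385L)
  expect_identical(sample_size(0.783, 0.05, 1.96, 1.5), 392L)
  # doubling the margin divides n by ~4
  expect_equal(sample_size(0.5, 0.10, 1.96, 1.0), 97L)
  expect_error(sample_size(1.2, 0.05), "outside")
  expect_error(sample_size(0.5, 0), "outside")
  expect_error(sample_size(0.5, 0.05, deff = 0.5), "outside")

  # monotone in p(1-p), z, deff; decreasing in margin
  base <- sample_size(0.3, 0.05)
  expect_gte(sample_size(0.5, 0.05), base)
  expect_gte(sample_size(0.3, 0.05, z = 2.58), base)
  expect_gte(sample_size(0.3, 0.05, deff = 2), base)
  expect_lte(sample_size(0.3, 0.08), base)
})
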