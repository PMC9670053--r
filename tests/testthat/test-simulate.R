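# seeded synthetic cohort generator

test_that("identical config and seed give byte-identical cohorts", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n = 300, seed = 7)
  a <- file.path(dir, "a.csv"); b <- file.path(dir, "b.csv")
  write_cohort(generate_cohort(cfg), a)
  write_cohort(generate_cohort(cfg), b)
  expect_identical(readLines(a), readLines(b))

  other <- generate_cohort(sim_config(n = 300, seed = 8))
  expect_false(identical(other$total_cost,
                         generate_cohort(cfg)$total_cost))
})

test_that("categorical draws hit the configured frequencies at large n", {
  coh <- generate_cohort(sim_config(n = 100000, seed = 21))
  p <- table(coh$disability_class)[c("temporary_total", "permanent_partial",
                                     "permanent_total", "death")] / nrow(coh)
  expect_true(all(abs(as.numeric(p) -
                        c(0.397, 0.506, 0.058, 0.039)) < 0.01))
  expect_lt(abs(mean(coh$sex == "male") - 0.979), 0.005)
  expect_lt(abs(mean(coh$unsafe_act) - 0.9384), 0.01)
})

test_that("gamma cost draws have the configured mean when covariate effects are off", {
  cfg <- sim_config(n = 50000, seed = 5,
                    cost_model = list(beta0 = log(1000),
                                      beta = c(long_term_absence = 0,
                                               severe = 0, unsafe_act = 0,
                                               sleeping_disorder = 0,
                                               comorbidity = 0),
                                      shape = 2, mean_total = 1000))
  coh <- generate_cohort(cfg)
  expect_equal(mean(coh$total_cost), 1000, tolerance = 0.02)
})

test_that("workday and wage medians are calibrated to the study cohort", {
  meds <- t(vapply(1:200, function(s) {
    coh <- generate_cohort(sim_config(n = 1200, seed = s))
    c(median(coh$workdays_lost), median(coh$daily_wage))
  }, numeric(2)))
  expect_lt(abs(mean(meds[, 1]) - 21.48), 2)
  expect_lt(abs(mean(meds[, 2]) - 207.6), 10)
})

test_that("workday mixture respects the bin partition and right skew", {
  coh <- generate_cohort(sim_config(n = 20000, seed = 13))
  s <- summarize_workdays(coh)
  expect_equal(unname(s$proportions), c(0.04, 0.745, 0.215), tolerance = 0.1)
  expect_true(all(coh$workdays_lost >= 0 & coh$workdays_lost <= 365))
  expect_gt(mean(coh$workdays_lost), median(coh$workdays_lost)) # right skew
})

test_that("copula-correlated covariates remain calibrated marginally", {
  cfg <- sim_config(n = 30000, seed = 17, covariate_correlation = 0.4)
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(coh$sleeping_disorder) - 0.5599), 0.01)
  expect_lt(abs(mean(coh$comorbidity) - 0.5599), 0.01)
  # positive dependence induced by the shared factor
  expect_gt(cor(coh$sleeping_disorder, coh$comorbidity), 0.1)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(n = 0), "outside")
  expect_error(sim_config(disability_probs = c(0.5, 0.4, 0.05, 0.04)),
               "sum to 1")
  expect_error(sim_config(cost_model = list(beta0 = NULL, beta = c(a = 0),
                                            shape = -1, mean_total = 10)),
               "outside")
  bad_bins <- sim_config(workday_model = list(
    bin_masses = c(0.6, 0.2, 0.2), target_median = 21.48, sdlog_mid = 0.5,
    meanlog_high = log(12), sdlog_high = 0.8, max_days = 365))
  expect_error(generate_cohort(bad_bins), "median outside")
})

test_that("the fixture suite contains the documented hand-computable cases", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture_suite(dir)
  expect_true(all(file.exists(paths)))
  expect_equal(summarize_workdays(read_cohort(paths[["even"]]))$median_days, 2.5)
  expect_equal(summarize_workdays(read_cohort(paths[["odd"]]))$median_days, 3)
  expect_equal(summarize_workdays(read_cohort(paths[["zero"]]))$total_days, 0)
})
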