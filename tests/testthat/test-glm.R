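# gamma log-link GLM by IRLS

test_that("the intercept-only fit recovers the sample mean", {
  fit <- fit_gamma_log_glm(matrix(nrow = 3, ncol = 0), c(1, 2, 3))
  expect_equal(unname(fit$exp_b[["(Intercept)"]]), 2, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS agrees with the reference GLM fitter on random small datasets", {
  withr::local_seed(101)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rnorm(n)
    mu <- exp(1 + 0.5 * x1 - 0.3 * x2)
    y <- rgamma(n, shape = 2, rate = 2 / mu)
    X <- cbind(x1 = x1, x2 = x2)
    fit <- fit_gamma_log_glm(X, y)
    ref <- suppressWarnings(glm(y ~ x1 + x2, family = Gamma(link = "log")))
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("coefficients maximize the likelihood: brute-force grid agreement", {
  x1 <- c(0, 0, 0, 1, 1, 1)
  y <- c(1.2, 2.1, 3.3, 4.4, 5.0, 8.7)
  fit <- fit_gamma_log_glm(cbind(x1 = x1), y)
  oracle <- grid_glm_oracle(x1, y)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
})

test_that("the fit is invariant to row permutation", {
  withr::local_seed(7)
  coh <- generate_cohort(sim_config(n = 300, seed = 7))
  X <- design_matrix(coh)
  fit <- fit_gamma_log_glm(X, coh$total_cost)
  perm <- sample(nrow(coh))
  fit_p <- fit_gamma_log_glm(X[perm, ], coh$total_cost[perm])
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-10)
  expect_equal(fit$deviance, fit_p$deviance, tolerance = 1e-10)
})

test_that("IRLS converges quickly on well-conditioned simulated designs", {
  withr::local_seed(55)
  for (i in 1:100) {
    p <- sample(2:5, 1)
    n <- 50 * (p + 1)
    X <- matrix(rbinom(n * p, 1, runif(p, 0.2, 0.8)), n, p)
    colnames(X) <- paste0("x", 1:p)
    beta <- runif(p, -0.5, 0.5)
    mu <- exp(5 + drop(X %*% beta))
    y <- rgamma(n, shape = 2, rate = 2 / mu)
    fit <- fit_gamma_log_glm(X, y)
    expect_true(fit$converged)
    expect_lte(fit$n_iterations, 25)
  }
})

test_that("simulated effect sizes are recovered inside their Wald intervals", {
  withr::local_seed(12)
  n <- 5000
  x1 <- rbinom(n, 1, 0.94)
  x2 <- rbinom(n, 1, 0.82)
  truth <- c(log(1000), log(1.44), log(0.85))
  mu <- exp(truth[1] + truth[2] * x1 + truth[3] * x2)
  y <- rgamma(n, shape = 2, rate = 2 / mu)
  fit <- fit_gamma_log_glm(cbind(unsafe = x1, long_absence = x2), y)
  tab <- exp_coefficient_table(fit)
  expect_true(all(tab$ci_low <= tab$exp_b & tab$exp_b <= tab$ci_high))
  expect_true(all(fit$ci95[, "lower"] <= exp(truth) &
                    exp(truth) <= fit$ci95[, "upper"]))
  expect_true(all(exp(truth[2:3]) >= tab$ci_low &
                    exp(truth[2:3]) <= tab$ci_high))
})

test_that("a null predictor yields a unit cost ratio with a CI spanning one", {
  # y identical across the two predictor groups: b1 = 0 exactly
  x1 <- rep(c(0, 1), each = 4)
  y <- rep(c(2, 3, 5, 8), 2)
  fit <- fit_gamma_log_glm(cbind(grp = x1), y)
  tab <- exp_coefficient_table(fit)
  expect_equal(tab$exp_b, 1, tolerance = 1e-8)
  expect_lt(tab$ci_low, 1)
  expect_gt(tab$ci_high, 1)
})

test_that("degenerate inputs raise errors and non-convergence is reported", {
  X <- cbind(x = c(0, 1, 0, 1, 0, 1))
  expect_error(fit_gamma_log_glm(X, c(1, 2, 0, 4, 5, 6)), "positive")
  expect_error(fit_gamma_log_glm(cbind(a = rep(1, 6), b = rep(2, 6)),
                                 1:6), "rank-deficient")
  expect_error(fit_gamma_log_glm(matrix(rnorm(12), 2, 6) + 10, c(1, 2)),
               "more observations")
  withr::local_seed(2)
  y <- rgamma(40, 2, 0.1)
  x <- rbinom(40, 1, 0.5)
  expect_warning(bad <- fit_gamma_log_glm(cbind(x = x), y, max_iter = 1),
                 "did not converge")
  expect_false(bad$converged)
  expect_error(exp_coefficient_table(bad), "converge")
})

test_that("design_matrix encodes two-level factors and refuses non-binary columns", {
  coh <- generate_cohort(sim_config(n = 50, seed = 4))
  X <- design_matrix(coh)
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_true(all(X %in% c(0, 1)))
  expect_equal(unname(X[, "severity"]), as.numeric(coh$severity == "severe"))
  expect_equal(unname(X[, "ppe_inconsistent"]),
               as.numeric(coh$ppe_use == "inconsistent"))
  expect_error(design_matrix(coh, "daily_wage"), "not binary")
  expect_error(design_matrix(coh, "nope"), "unknown predictor")
})
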