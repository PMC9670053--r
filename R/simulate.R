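#' @title Seeded synthetic claim cohorts
#' @description
#' Generates cohorts whose marginal distributions match the published
#' summary structure of an Ethiopian manufacturing-industry compensation
#' claims registry: categorical frequencies of the descriptive tables, a
#' right-skewed workday-loss mixture with median near 21.48 days, a
#' log-normal daily wage with median 207.6 ETB, and a per-claim total cost
#' drawn from a gamma distribution whose log mean is linear in the clinical
#' covariates. Only printed marginals are emulated; the joint distribution
#' of the real cohort is unknown and not targeted.
#' @name synthetic-cohorts
NULL

# Table-frequency defaults. Body-part counts use 208 for leg_foot (17.3% of
# 1200); the published table's count for that row is a typo exceeding n.
.default_body_part <- c(hand_finger = 720, leg_foot = 208, head_neck = 140,
                        eye = 48, ear = 8, back_vertebra = 8,
                        chest_shoulder = 8, teeth = 32, multiple = 29)
.default_cause <- c(slippery_surface = 258, contact_objects = 123,
                    fall_from_height = 271, harmful_substances = 141,
                    transport_accident = 63, fire_explosion = 57,
                    machine = 52, mishandling = 53, lifting_heavy = 27,
                    hand_tools = 52, sweaty_palms = 103)

#' Simulation configuration for synthetic cohorts
#'
#' All distributional knobs of the generator, with defaults calibrated to the
#' published cohort summaries (n = 1200 claims over calendar year 2021).
#'
#' @param n Number of claims (default 1200).
#' @param seed Integer RNG seed; cohorts are a pure function of the config.
#' @param disability_probs Probabilities of (temporary_total,
#'   permanent_partial, permanent_total, death); default
#'   (0.397, 0.506, 0.058, 0.039).
#' @param sex_prob_male Probability a claimant is male (default 0.979).
#' @param body_part_probs,cause_probs Category probabilities; defaults are
#'   the published frequencies normalised.
#' @param timing_probs Probabilities of (morning, afternoon, night) injury
#'   timing; default (0.3644, 0.2069, 0.4287).
#' @param covariate_prevalence Named prevalences of the binary covariates:
#'   `unsafe_act` 0.9384, `sleeping_disorder` 0.5599, `comorbidity` 0.5599,
#'   `severe` 0.6021, `ppe_inconsistent` 0.6514, `injury_prevents_work`
#'   0.6020.
#' @param workday_model Three-component mixture for days of full absence:
#'   `bin_masses` on bins under 5 / 5--30 / over 30 days (default
#'   0.04, 0.745, 0.215); uniform on 0..4; discretised truncated log-normal
#'   on 5..30 whose location is solved so the overall median equals
#'   `target_median` (default 21.48 days, spread `sdlog_mid` 0.5); shifted
#'   truncated log-normal on 31..`max_days` (location `meanlog_high`,
#'   spread `sdlog_high`).
#' @param wage_model Log-normal daily wage: `median` 207.6 ETB/day and
#'   `sdlog` 0.28 (chosen so the implied SD is close to the reported 60.7).
#' @param cost_model Per-claim total cost: gamma with `shape` k (default 2;
#'   dispersion is not reported for the real cohort) and mean
#'   `exp(beta0 + sum(beta_j x_j))` over the five covariates of the
#'   published cost model. `beta` defaults to the log of the published
#'   multiplicative effects: long_term_absence ln 0.85, severe ln 1.11,
#'   unsafe_act ln 1.44, sleeping_disorder ln 0.90, comorbidity ln 0.85.
#'   `beta0 = NULL` solves the intercept so the marginal mean cost equals
#'   `mean_total` (default 18823.03 ETB, the published grand total divided
#'   by 1200 claims) at the generator's covariate prevalences.
#' @param medical_model Log-normal medical cost, `median` 3000 ETB,
#'   `sdlog` 0.75.
#' @param compensation_model Per-disability-class log-normal compensation.
#'   `class_medians = NULL` takes class medians proportional to the
#'   published class totals per claim, rescaled by a common factor solved so
#'   the cohort-wide compensation median equals `overall_median`
#'   (default 3426.32 ETB); `sdlog` 0.7.
#' @param covariate_correlation Equicorrelation of the Gaussian copula used
#'   to draw the binary covariates jointly; 0 (the default) draws them
#'   independently at the stated prevalences. The registry publishes no
#'   joint distribution, so correlation is an exploratory knob only.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n = 1200,
                       seed = 1L,
                       disability_probs = c(temporary_total = 0.397,
                                            permanent_partial = 0.506,
                                            permanent_total = 0.058,
                                            death = 0.039),
                       sex_prob_male = 0.979,
                       body_part_probs = .default_body_part /
                         sum(.default_body_part),
                       cause_probs = .default_cause / sum(.default_cause),
                       timing_probs = c(morning = 0.3644, afternoon = 0.2069,
                                        night = 0.4287),
                       covariate_prevalence = c(unsafe_act = 0.9384,
                                                sleeping_disorder = 0.5599,
                                                comorbidity = 0.5599,
                                                severe = 0.6021,
                                                ppe_inconsistent = 0.6514,
                                                injury_prevents_work = 0.6020),
                       workday_model = list(bin_masses = c(0.04, 0.745, 0.215),
                                            target_median = 21.48,
                                            sdlog_mid = 0.5,
                                            meanlog_high = log(12),
                                            sdlog_high = 0.8,
                                            max_days = 365),
                       wage_model = list(median = 207.6, sdlog = 0.28),
                       cost_model = list(beta0 = NULL,
                                         beta = c(long_term_absence = log(0.85),
                                                  severe = log(1.11),
                                                  unsafe_act = log(1.44),
                                                  sleeping_disorder = log(0.90),
                                                  comorbidity = log(0.85)),
                                         shape = 2,
                                         mean_total = 18823.03),
                       medical_model = list(median = 3000, sdlog = 0.75),
                       compensation_model = list(class_medians = NULL,
                                                 sdlog = 0.7,
                                                 overall_median = 3426.32),
                       covariate_correlation = 0) {
  check_number(n, "n", 1)
  stopifnot(n == floor(n))
  check_number(seed, "seed")
  check_prob_vector(disability_probs, "disability_probs")
  check_prob_vector(body_part_probs, "body_part_probs")
  check_prob_vector(cause_probs, "cause_probs")
  check_prob_vector(timing_probs, "timing_probs")
  check_number(sex_prob_male, "sex_prob_male", 0, 1)
  stopifnot(all(covariate_prevalence >= 0 & covariate_prevalence <= 1))
  check_prob_vector(workday_model$bin_masses, "workday_model$bin_masses")
  check_number(workday_model$target_median, "workday_model$target_median",
               5, 30, strict_lower = TRUE, strict_upper = TRUE)
  check_number(cost_model$shape, "cost_model$shape", 0, strict_lower = TRUE)
  check_number(covariate_correlation, "covariate_correlation", 0, 1,
               strict_upper = TRUE)

  structure(list(n = as.integer(n), seed = as.integer(seed),
                 disability_probs = disability_probs,
                 sex_prob_male = sex_prob_male,
                 body_part_probs = body_part_probs,
                 cause_probs = cause_probs,
                 timing_probs = timing_probs,
                 covariate_prevalence = covariate_prevalence,
                 workday_model = workday_model,
                 wage_model = wage_model,
                 cost_model = cost_model,
                 medical_model = medical_model,
                 compensation_model = compensation_model,
                 covariate_correlation = covariate_correlation),
            class = "sim_config")
}

# quantile-transform sampler of a log-normal truncated to [lo, hi]
.rlnorm_trunc <- function(u, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(p_lo + u * (p_hi - p_lo), meanlog, sdlog)
}

# Solve the mid-component log-normal location so that the overall mixture
# median hits the target: the target must sit at quantile
# (0.5 - w1) / w2 within the 5..30 component.
.solve_workday_meanlog <- function(wm) {
  w <- wm$bin_masses
  q <- (0.5 - w[1]) / w[2]
  if (q <= 0 || q >= 1) {
    stop("workday bin masses place the median outside the 5-30 day component",
         call. = FALSE)
  }
  f <- function(mu) {
    p_lo <- stats::plnorm(5, mu, wm$sdlog_mid)
    p_hi <- stats::plnorm(30, mu, wm$sdlog_mid)
    stats::qlnorm(p_lo + q * (p_hi - p_lo), mu, wm$sdlog_mid) -
      wm$target_median
  }
  stats::uniroot(f, c(log(2), log(120)), tol = 1e-10)$root
}

# Common scale factor for the per-class compensation medians so the mixture
# (over disability-class probabilities) has the requested overall median.
.solve_compensation_scale <- function(base_medians, sdlog, probs,
                                      overall_median) {
  f <- function(s) {
    sum(probs * stats::plnorm(overall_median, log(s * base_medians), sdlog)) -
      0.5
  }
  stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root
}

#' Generate a synthetic injury cohort
#'
#' Draws `config$n` claim records under `config$seed`; identical configs give
#' byte-identical cohorts. Workdays lost come from the three-component
#' mixture described in [sim_config()]; the per-claim `total_cost` is
#' gamma-distributed with log-linear mean in the five cost-model covariates.
#' Monetary values are rounded to cents, so cohorts survive a CSV round trip
#' exactly.
#'
#' @param config A [sim_config()].
#' @return An `injury_cohort` with the optional `total_cost` column.
#' @examples
#' coh <- generate_cohort(sim_config(n = 200, seed = 42))
#' summarize_workdays(coh)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  wm <- config$workday_model
  mu_mid <- .solve_workday_meanlog(wm)
  comp_base <- config$compensation_model$class_medians
  if (is.null(comp_base)) {
    # published class compensation totals divided by class counts fix the
    # ratios; the common scale is solved to hit the overall median
    comp_base <- c(temporary_total = 479188.56 / 476,
                   permanent_partial = 506188.34 / 607,
                   permanent_total = 752189.02 / 70,
                   death = 779188.80 / 47)
    s <- .solve_compensation_scale(comp_base, config$compensation_model$sdlog,
                                   config$disability_probs,
                                   config$compensation_model$overall_median)
    comp_medians <- s * comp_base
  } else {
    comp_medians <- comp_base
  }

  with_local_seed(config$seed, {
    df <- data.frame(
      worker_id = sprintf("W%05d", seq_len(n)),
      sex = ifelse(stats::runif(n) < config$sex_prob_male, "male", "female"),
      disability_class = sample(names(config$disability_probs), n,
                                replace = TRUE,
                                prob = config$disability_probs),
      body_part = sample(names(config$body_part_probs), n, replace = TRUE,
                         prob = config$body_part_probs),
      cause = sample(names(config$cause_probs), n, replace = TRUE,
                     prob = config$cause_probs),
      timing = sample(names(config$timing_probs), n, replace = TRUE,
                      prob = config$timing_probs),
      stringsAsFactors = FALSE
    )

    # workday-loss mixture
    comp <- sample.int(3, n, replace = TRUE, prob = wm$bin_masses)
    days <- integer(n)
    n1 <- sum(comp == 1)
    days[comp == 1] <- sample(0:4, n1, replace = TRUE)
    u2 <- stats::runif(sum(comp == 2))
    days[comp == 2] <- pmin(30L, pmax(5L, as.integer(round(
      .rlnorm_trunc(u2, mu_mid, wm$sdlog_mid, 5, 30)))))
    u3 <- stats::runif(sum(comp == 3))
    extra <- .rlnorm_trunc(u3, wm$meanlog_high, wm$sdlog_high,
                           1, wm$max_days - 30)
    days[comp == 3] <- pmax(31L, as.integer(round(30 + extra)))
    df$workdays_lost <- days

    df$daily_wage <- round_half_up(
      stats::rlnorm(n, log(config$wage_model$median), config$wage_model$sdlog))
    df$medical_cost <- round_half_up(
      stats::rlnorm(n, log(config$medical_model$median),
                    config$medical_model$sdlog))
    df$compensation <- round_half_up(
      stats::rlnorm(n, log(comp_medians[df$disability_class]),
                    config$compensation_model$sdlog))

    # binary covariates: independent Bernoulli, or a Gaussian copula with
    # equicorrelation when requested
    prev <- config$covariate_prevalence
    rho <- config$covariate_correlation
    if (rho > 0) {
      z0 <- stats::rnorm(n)
      draws <- vapply(names(prev), function(nm) {
        z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
        z < stats::qnorm(prev[[nm]])
      }, logical(n))
    } else {
      draws <- vapply(names(prev), function(nm) {
        stats::runif(n) < prev[[nm]]
      }, logical(n))
    }
    draws <- as.data.frame(matrix(as.logical(draws), nrow = n,
                                  dimnames = list(NULL, names(prev))))
    df$unsafe_act <- draws$unsafe_act
    df$sleeping_disorder <- draws$sleeping_disorder
    df$comorbidity <- draws$comorbidity
    df$severity <- ifelse(draws$severe, "severe", "minor")
    df$ppe_use <- ifelse(draws$ppe_inconsistent, "inconsistent", "consistent")
    df$injury_prevents_work <- draws$injury_prevents_work

    # gamma total cost with log-linear mean
    cm <- config$cost_model
    x <- cbind(long_term_absence = as.numeric(df$workdays_lost >
                                                .long_term_threshold),
               severe = as.numeric(draws$severe),
               unsafe_act = as.numeric(draws$unsafe_act),
               sleeping_disorder = as.numeric(draws$sleeping_disorder),
               comorbidity = as.numeric(draws$comorbidity))
    beta <- cm$beta[colnames(x)]
    beta0 <- cm$beta0
    if (is.null(beta0)) {
      w <- wm$bin_masses
      marg <- c(long_term_absence = unname(w[2] + w[3]),
                severe = unname(prev[["severe"]]),
                unsafe_act = unname(prev[["unsafe_act"]]),
                sleeping_disorder = unname(prev[["sleeping_disorder"]]),
                comorbidity = unname(prev[["comorbidity"]]))
      beta0 <- log(cm$mean_total) - sum(beta * marg[names(beta)])
    }
    mu <- exp(beta0 + drop(x %*% beta))
    df$total_cost <- pmax(0.01, round_half_up(
      stats::rgamma(n, shape = cm$shape, rate = cm$shape / mu)))

    as_injury_cohort(df, quiet = TRUE)
  })
}

#' Write the small CSV fixtures used by the test suite
#'
#' Emits deterministic, hand-sized cohort files: a clean 10-row cohort, a
#' file containing invalid rows (negative workdays, missing sex, zero wage),
#' even- and odd-sized cohorts with hand-computable medians, and a
#' degenerate cohort in which nobody lost a workday.
#'
#' @param outdir Directory to write into (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
generate_fixture_suite <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create directory: ", outdir,
                                call. = FALSE)
  base_row <- function(id, days, wage = 200, medical = 1000, comp = 500) {
    data.frame(worker_id = id, sex = "male",
               disability_class = "temporary_total", body_part = "hand_finger",
               cause = "machine", timing = "morning", workdays_lost = days,
               daily_wage = wage, medical_cost = medical, compensation = comp,
               unsafe_act = 1L, sleeping_disorder = 0L, comorbidity = 0L,
               severity = "minor", ppe_use = "consistent",
               injury_prevents_work = 1L, stringsAsFactors = FALSE)
  }
  rows <- function(days) {
    do.call(rbind, lapply(seq_along(days), function(i) {
      base_row(sprintf("W%03d", i), days[i])
    }))
  }
  paths <- c(clean = file.path(outdir, "clean_10.csv"),
             invalid = file.path(outdir, "invalid_rows.csv"),
             even = file.path(outdir, "even_n_median.csv"),
             odd = file.path(outdir, "odd_n_median.csv"),
             zero = file.path(outdir, "all_zero_workdays.csv"))
  utils::write.csv(rows(c(0, 2, 4, 5, 10, 21, 22, 30, 31, 90)),
                   paths["clean"], row.names = FALSE, quote = FALSE)
  bad <- rows(c(3, 7, 12, 20))
  bad$workdays_lost[2] <- -1          # invariant violation
  bad$sex[3] <- ""                    # missing demographics
  bad$daily_wage[4] <- 0              # invariant violation
  utils::write.csv(bad, paths["invalid"], row.names = FALSE, quote = FALSE)
  utils::write.csv(rows(c(1, 2, 3, 100)), paths["even"], row.names = FALSE,
                   quote = FALSE)  # median 2.5
  utils::write.csv(rows(c(1, 2, 3, 4, 100)), paths["odd"], row.names = FALSE,
                   quote = FALSE)  # median 3
  utils::write.csv(rows(rep(0, 6)), paths["zero"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
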