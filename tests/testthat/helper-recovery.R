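# Wald-interval coverage study: generate cohorts at the default effect
# sizes, refit, and record whether each true multiplicative effect falls
# inside its 95% interval.
cost_predictors <- c("long_term_absence", "severity", "unsafe_act",
                     "sleeping_disorder", "comorbidity")
true_exp_b <- c(long_term_absence = 0.85, severity = 1.11, unsafe_act = 1.44,
                sleeping_disorder = 0.90, comorbidity = 0.85)

ci_coverage_study <- function(n_reps = 200, n = 1200, base_seed = 1) {
  hits <- matrix(NA, n_reps, length(cost_predictors),
                 dimnames = list(NULL, cost_predictors))
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(sim_config(n = n, seed = base_seed * 100000 + r))
    fit <- fit_gamma_log_glm(design_matrix(coh, cost_predictors),
                             coh$total_cost)
    ci <- fit$ci95[cost_predictors, , drop = FALSE]
    hits[r, ] <- ci[, "lower"] <= true_exp_b & true_exp_b <= ci[, "upper"]
  }
  colMeans(hits)
}
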