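#' @title Friction-method indirect costs
#' @description
#' Indirect productivity losses borne by the employer are valued with the
#' friction cost method: lost output is counted only over the observed
#' absence (the friction-bounded lost workdays), priced at the median daily
#' wage, and inflated by multipliers reflecting that the cost of missed work
#' to the firm exceeds the wage. Absenteeism (full absence) uses a median
#' multiplier of 1.28; presenteeism (attending while impaired, producing
#' sub-normal output) uses 1.5:
#'
#' \deqn{AC = MLW \times NIE \times MDWE \times 1.28}
#' \deqn{PC = MLW \times NIE \times MDWE \times 1.5}
#'
#' where MLW is the median of lost workdays, NIE the number of injured
#' employees and MDWE the median daily wage.
#' @name friction-costing
NULL

#' Friction-method inputs
#'
#' @param mlw_absent Median lost workdays for absenteeism (days, >= 0).
#' @param mlw_present Median lost workdays for presenteeism; defaults to
#'   `mlw_absent`, the convention under which the published indirect totals
#'   reproduce exactly (no separate presenteeism duration is reported).
#' @param nie Number of injured employees (>= 1).
#' @param mdwe Median daily wage of the employees (ETB/day, > 0).
#' @return A `friction_inputs` list.
#' @export
friction_inputs <- function(mlw_absent, mlw_present = mlw_absent, nie, mdwe) {
  check_number(mlw_absent, "mlw_absent", 0)
  check_number(mlw_present, "mlw_present", 0)
  check_number(nie, "nie", 1)
  stopifnot(nie == floor(nie))
  check_number(mdwe, "mdwe", 0, strict_lower = TRUE)
  structure(list(mlw_absent = mlw_absent, mlw_present = mlw_present,
                 nie = as.integer(nie), mdwe = mdwe),
            class = "friction_inputs")
}

#' Friction-method multipliers
#'
#' @param absenteeism_multiplier Multiplier on absenteeism wage-days
#'   (default 1.28, the median multiplier reflecting that missed work costs
#'   the firm more than the wage).
#' @param presenteeism_multiplier Multiplier on presenteeism wage-days
#'   (default 1.5).
#' @return A `friction_params` list.
#' @export
friction_params <- function(absenteeism_multiplier = 1.28,
                            presenteeism_multiplier = 1.5) {
  check_number(absenteeism_multiplier, "absenteeism_multiplier", 1)
  check_number(presenteeism_multiplier, "presenteeism_multiplier", 1)
  structure(list(absenteeism_multiplier = absenteeism_multiplier,
                 presenteeism_multiplier = presenteeism_multiplier),
            class = "friction_params")
}

# derive friction inputs from a cohort; `cap_days` optionally truncates each
# observed absence at a friction-period bound before taking the median
.cohort_friction_inputs <- function(cohort, cap_days = Inf) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  d <- pmin(cohort$workdays_lost, cap_days)
  friction_inputs(mlw_absent = stats::median(d),
                  nie = nrow(cohort),
                  mdwe = stats::median(cohort$daily_wage))
}

#' Absenteeism cost
#'
#' `mlw_absent * nie * mdwe * absenteeism_multiplier`, in ETB.
#'
#' @param inputs A [friction_inputs()].
#' @param params A [friction_params()].
#' @return Absenteeism cost (ETB, full precision).
#' @examples
#' absenteeism_cost(friction_inputs(21.48, nie = 1200, mdwe = 207.6),
#'                  friction_params())
#' @export
absenteeism_cost <- function(inputs, params = friction_params()) {
  stopifnot(inherits(inputs, "friction_inputs"),
            inherits(params, "friction_params"))
  inputs$mlw_absent * inputs$nie * inputs$mdwe * params$absenteeism_multiplier
}

#' Presenteeism cost
#'
#' `mlw_present * nie * mdwe * presenteeism_multiplier`, in ETB.
#'
#' @inheritParams absenteeism_cost
#' @return Presenteeism cost (ETB, full precision).
#' @export
presenteeism_cost <- function(inputs, params = friction_params()) {
  stopifnot(inherits(inputs, "friction_inputs"),
            inherits(params, "friction_params"))
  inputs$mlw_present * inputs$nie * inputs$mdwe * params$presenteeism_multiplier
}

#' Indirect-cost report (absenteeism + presenteeism)
#'
#' Accepts either an `injury_cohort` — in which case MLW and MDWE are the
#' cohort medians and NIE its size — or explicit [friction_inputs()].
#'
#' @param x An `injury_cohort` or a `friction_inputs`.
#' @param params A [friction_params()].
#' @param cap_days Optional friction-period cap (days) applied to each
#'   observed absence before the median is taken; default uncapped, treating
#'   observed lost workdays as already friction-bounded. Ignored when `x`
#'   is a `friction_inputs`.
#' @return An `indirect_cost_report` list: `absenteeism`, `presenteeism`,
#'   `total_indirect`, `average_per_case`, `inputs`, `params`.
#' @export
indirect_cost_report <- function(x, params = friction_params(),
                                 cap_days = Inf) {
  inputs <- if (inherits(x, "injury_cohort")) {
    .cohort_friction_inputs(x, cap_days = cap_days)
  } else if (inherits(x, "friction_inputs")) {
    x
  } else {
    stop("`x` must be an injury_cohort or friction_inputs", call. = FALSE)
  }
  ac <- absenteeism_cost(inputs, params)
  pc <- presenteeism_cost(inputs, params)
  structure(list(absenteeism = ac,
                 presenteeism = pc,
                 total_indirect = ac + pc,
                 average_per_case = (ac + pc) / inputs$nie,
                 inputs = inputs,
                 params = params),
            class = "indirect_cost_report")
}

#' @export
print.indirect_cost_report <- function(x, ...) {
  cat("Friction-method indirect costs\n")
  cat(sprintf("  inputs: MLW %.2f / %.2f days, NIE %d, MDWE %.2f ETB/day\n",
              x$inputs$mlw_absent, x$inputs$mlw_present, x$inputs$nie,
              x$inputs$mdwe))
  cat(sprintf("  absenteeism  (x %.2f) %16.2f ETB\n",
              x$params$absenteeism_multiplier, round_half_up(x$absenteeism)))
  cat(sprintf("  presenteeism (x %.2f) %16.2f ETB\n",
              x$params$presenteeism_multiplier, round_half_up(x$presenteeism)))
  cat(sprintf("  total indirect        %16.2f ETB\n",
              round_half_up(x$total_indirect)))
  cat(sprintf("  average per case      %16.2f ETB\n",
              round_half_up(x$average_per_case)))
  invisible(x)
}
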