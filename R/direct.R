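#' @title Top-down direct costs
#' @description
#' Direct costs (medical care plus compensation payments) are estimated
#' top-down: the median medical cost and median compensation per claim are
#' summed and multiplied by the total number of claims, and compensation
#' totals are broken down by disability class. Medians rather than means are
#' used because claim costs are strongly right-skewed.
#' @name direct-costing
NULL

#' Median of a cost vector
#'
#' Order-statistic median with the mean-of-middle-two convention for even
#' sample sizes (the convention used throughout the package).
#'
#' @param values Non-empty numeric vector of costs (ETB).
#' @return The median cost.
#' @examples
#' median_cost(c(1, 2, 3, 4)) # 2.5
#' @export
median_cost <- function(values) {
  if (!is.numeric(values) || length(values) == 0 || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  stats::median(values)
}

#' Top-down direct-cost report
#'
#' Per-claim medians of medical cost and compensation, their sum (the median
#' direct cost per victim), the top-down total `median_direct_per_victim *
#' n_claims`, and compensation totals by disability class. Employer premium
#' payments, when supplied, are carried as a pass-through reporting field
#' and excluded from the direct total.
#'
#' @param cohort An `injury_cohort`.
#' @param premium Optional premium payment total (ETB) to report alongside.
#' @return A `direct_cost_report` list: `n_claims`, `median_medical`,
#'   `median_compensation`, `median_direct_per_victim`, `total_direct`,
#'   `compensation_by_class`, `total_compensation`, `premium`.
#' @export
direct_cost_report <- function(cohort, premium = NA_real_) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  med_med <- median_cost(cohort$medical_cost)
  med_comp <- median_cost(cohort$compensation)
  by_class <- vapply(split(cohort$compensation, factor(
    cohort$disability_class, levels = cohort_levels$disability_class)),
    sum, numeric(1))
  structure(list(
    n_claims = nrow(cohort),
    median_medical = med_med,
    median_compensation = med_comp,
    median_direct_per_victim = med_med + med_comp,
    total_direct = (med_med + med_comp) * nrow(cohort),
    compensation_by_class = by_class,
    total_compensation = sum(by_class),
    premium = premium
  ), class = "direct_cost_report")
}

#' @export
print.direct_cost_report <- function(x, ...) {
  cat(sprintf("Direct costs over %d claims (top-down)\n", x$n_claims))
  cat(sprintf("  median medical         %14.2f ETB\n",
              round_half_up(x$median_medical)))
  cat(sprintf("  median compensation    %14.2f ETB\n",
              round_half_up(x$median_compensation)))
  cat(sprintf("  median direct / victim %14.2f ETB\n",
              round_half_up(x$median_direct_per_victim)))
  cat(sprintf("  total direct           %14.2f ETB\n",
              round_half_up(x$total_direct)))
  cat("  compensation by class:\n")
  for (cl in names(x$compensation_by_class)) {
    cat(sprintf("    %-18s %14.2f ETB\n", cl,
                round_half_up(x$compensation_by_class[[cl]])))
  }
  cat(sprintf("  total compensation     %14.2f ETB\n",
              round_half_up(x$total_compensation)))
  if (!is.na(x$premium)) {
    cat(sprintf("  premium (pass-through) %14.2f ETB\n",
                round_half_up(x$premium)))
  }
  invisible(x)
}

#' Allocate a known total expenditure across categories
#'
#' Top-down allocation: each category receives `total * w_c / sum(w)`,
#' rounded to cents with a largest-remainder correction so the allocations
#' sum exactly to the (cent-rounded) total.
#'
#' @param known_total Total expenditure (ETB).
#' @param weights Named non-negative weights, not all zero.
#' @return Named numeric vector of allocations summing to
#'   `round_half_up(known_total)`.
#' @examples
#' allocate_total(10, c(a = 1, b = 2)) # a 3.33, b 6.67
#' @export
allocate_total <- function(known_total, weights) {
  check_number(known_total, "known_total", 0)
  if (!is.numeric(weights) || length(weights) == 0 || anyNA(weights)) {
    stop("`weights` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  total_cents <- round(round_half_up(known_total, 2) * 100)
  raw_cents <- total_cents * weights / sum(weights)
  alloc <- floor(raw_cents)
  short <- round(total_cents - sum(alloc))
  if (short > 0) {
    frac <- raw_cents - alloc
    take <- order(frac, decreasing = TRUE)[seq_len(short)]
    alloc[take] <- alloc[take] + 1
  }
  out <- alloc / 100
  names(out) <- names(weights)
  out
}
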