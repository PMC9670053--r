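#' @title Injury claim cohort: data model and CSV input/output
#' @description
#' A cohort is one row per injured worker drawn from employer compensation
#' claim records over a fixed reference period. Categorical codings follow
#' the claim-record structure of Ethiopian manufacturing-industry workers'
#' compensation data: a four-level disability classification
#' (temporary total, permanent partial, permanent total, death), injured body
#' part, cause of event, and the binary personal/clinical covariates used in
#' the cost model.
#' @name cohort
NULL

# canonical factor levels -----------------------------------------------------

#' Categorical level sets of the claim-record schema
#'
#' Named list of admissible levels for each categorical column of a cohort
#' CSV. Exported so callers can build valid records programmatically.
#'
#' @format A named list of character vectors.
#' @export
cohort_levels <- list(
  sex              = c("male", "female"),
  disability_class = c("temporary_total", "permanent_partial",
                       "permanent_total", "death"),
  body_part        = c("hand_finger", "leg_foot", "head_neck", "eye", "ear",
                       "back_vertebra", "chest_shoulder", "teeth", "multiple"),
  cause            = c("slippery_surface", "contact_objects", "fall_from_height",
                       "harmful_substances", "transport_accident",
                       "fire_explosion", "machine", "mishandling",
                       "lifting_heavy", "hand_tools", "sweaty_palms"),
  timing           = c("morning", "afternoon", "night"),
  severity         = c("minor", "severe"),
  ppe_use          = c("consistent", "inconsistent")
)

.bool_cols <- c("unsafe_act", "sleeping_disorder", "comorbidity",
                "injury_prevents_work")
.money_cols <- c("daily_wage", "medical_cost", "compensation")

.required_cols <- c("worker_id", "sex", "disability_class", "body_part",
                    "cause", "timing", "workdays_lost", "daily_wage",
                    "medical_cost", "compensation", .bool_cols[1:3],
                    "severity", "ppe_use", "injury_prevents_work")
.optional_cols <- c("age", "total_cost")

# days of full absence strictly beyond which an absence counts as long-term
.long_term_threshold <- 5

# row-level invariant screen; returns character reason or NA
.row_problem <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, msg, reason)
  }
  reason <- flag(df$workdays_lost < 0, "workdays_lost < 0")
  reason <- flag(df$workdays_lost != floor(df$workdays_lost),
                 "workdays_lost not a whole number of days")
  reason <- flag(df$daily_wage <= 0, "daily_wage <= 0")
  reason <- flag(df$medical_cost < 0, "medical_cost < 0")
  reason <- flag(df$compensation < 0, "compensation < 0")
  for (col in names(cohort_levels)) {
    reason <- flag(!(df[[col]] %in% cohort_levels[[col]]),
                   sprintf("invalid %s level", col))
  }
  for (col in .bool_cols) {
    reason <- flag(!(df[[col]] %in% c(TRUE, FALSE)),
                   sprintf("%s not interpretable as 0/1", col))
  }
  if ("total_cost" %in% names(df)) {
    reason <- flag(!is.na(df$total_cost) & df$total_cost <= 0,
                   "total_cost <= 0")
  }
  reason
}

#' Construct a validated injury cohort
#'
#' Builds an `injury_cohort` from a data frame of claim records, applying the
#' record-level inclusion rules: rows violating field invariants (negative
#' workdays, non-positive wage, negative costs, unknown category levels) are
#' rejected with row-indexed diagnostics, and rows with missing sex — or
#' missing age, when an `age` column is supplied — are excluded and counted,
#' mirroring the registry exclusion criteria under which records lacking
#' basic demographics are unusable.
#'
#' @param records Data frame with the columns listed under [read_cohort()].
#' @param reference_period Length-2 `Date` (start, end) of the costing year.
#' @param quiet If `TRUE`, suppress the warning summarising dropped rows.
#' @return An `injury_cohort`: a data frame of validated records (with the
#'   derived logical column `long_term_absence`, true when more than 5
#'   workdays were lost) carrying attributes
#'   `reference_period`, `excluded_missing_demographics` (count) and
#'   `rejected` (data frame of row index + reason).
#' @export
as_injury_cohort <- function(records,
                             reference_period = as.Date(c("2021-01-01",
                                                          "2021-12-30")),
                             quiet = FALSE) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c(names(cohort_levels), "worker_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in .bool_cols) {
    v <- records[[col]]
    if (!is.logical(v)) v <- as.logical(as.integer(as.character(v)))
    records[[col]] <- v
  }
  for (col in c("workdays_lost", .money_cols,
                intersect(.optional_cols, names(records)))) {
    records[[col]] <- as.numeric(records[[col]])
  }

  # demographic exclusions first (missing sex / missing age)
  demo_missing <- is.na(records$sex) | records$sex == ""
  if ("age" %in% names(records)) demo_missing <- demo_missing | is.na(records$age)
  n_demo <- sum(demo_missing)
  kept <- records[!demo_missing, , drop = FALSE]

  problem <- if (nrow(kept)) .row_problem(kept) else character(0)
  rejected <- data.frame(
    row = which(!demo_missing)[!is.na(problem)],
    reason = problem[!is.na(problem)],
    stringsAsFactors = FALSE
  )
  kept <- kept[is.na(problem), , drop = FALSE]

  if (!quiet && (n_demo > 0 || nrow(rejected) > 0)) {
    warning(sprintf(
      "dropped %d record(s) with missing demographics; rejected %d invalid row(s)",
      n_demo, nrow(rejected)), call. = FALSE)
  }
  if (nrow(kept) == 0) {
    stop("cohort is empty after validation", call. = FALSE)
  }
  if (anyDuplicated(kept$worker_id)) {
    stop("worker_id values must be unique", call. = FALSE)
  }
  stopifnot(length(reference_period) == 2)

  kept$long_term_absence <- kept$workdays_lost > .long_term_threshold
  ord <- c(.required_cols, intersect(.optional_cols, names(kept)),
           "long_term_absence")
  kept <- kept[, ord, drop = FALSE]
  rownames(kept) <- NULL
  structure(kept,
            reference_period = as.Date(reference_period),
            excluded_missing_demographics = n_demo,
            rejected = rejected,
            class = c("injury_cohort", "data.frame"))
}

#' Read an injury-claim cohort from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, header mandatory, booleans
#' coded 0/1. Required columns: `worker_id`, `sex`, `disability_class`,
#' `body_part`, `cause`, `timing`, `workdays_lost`, `daily_wage`,
#' `medical_cost`, `compensation`, `unsafe_act`, `sleeping_disorder`,
#' `comorbidity`, `severity`, `ppe_use`, `injury_prevents_work`. Optional:
#' `age` (used only for the missing-age exclusion rule), `total_cost`
#' (per-claim total cost in ETB, the response of [fit_gamma_log_glm()]).
#' Validation behaviour is that of [as_injury_cohort()].
#'
#' @param path Path to a CSV file.
#' @param reference_period,quiet Passed to [as_injury_cohort()].
#' @return An `injury_cohort`.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(path,
                        reference_period = as.Date(c("2021-01-01",
                                                     "2021-12-30")),
                        quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(worker_id = "character"),
                         fileEncoding = "UTF-8")
  as_injury_cohort(raw, reference_period = reference_period, quiet = quiet)
}

#' Write an injury cohort to CSV
#'
#' Writes the canonical column order with booleans as 0/1 so that
#' `read_cohort(write_cohort(x))` reproduces `x` field for field. The
#' derived `long_term_absence` flag is not written; it is recomputed on read.
#'
#' @param cohort An `injury_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (nrow(cohort) == 0) stop("refusing to write an empty cohort", call. = FALSE)
  out <- as.data.frame(cohort)
  out$long_term_absence <- NULL
  for (col in .bool_cols) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.injury_cohort <- function(x, ...) {
  rp <- attr(x, "reference_period")
  cat(sprintf("Injury cohort: %d claims, reference period %s to %s\n",
              nrow(x), rp[1], rp[2]))
  cat(sprintf("  excluded (missing demographics): %d; rejected (invalid): %d\n",
              attr(x, "excluded_missing_demographics"),
              nrow(attr(x, "rejected"))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}

# descriptive statistics ------------------------------------------------------

#' Summarise lost workdays
#'
#' Totals and bins the full-absence days of a cohort. The bins partition the
#' non-negative integers into under 5 days, 5 to 30 days inclusive, and over
#' 30 days — the ranges conventionally reported for short, typical and
#' prolonged post-injury absence. The median uses the mean-of-middle-two
#' convention for even cohort sizes.
#'
#' @param cohort An `injury_cohort`.
#' @return A `workday_summary` list: `n`, `total_days`, `median_days`,
#'   `counts` (named: `under_5`, `d5_to_30`, `over_30`) and `proportions`.
#' @export
summarize_workdays <- function(cohort) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  d <- cohort$workdays_lost
  counts <- c(under_5  = sum(d < 5),
              d5_to_30 = sum(d >= 5 & d <= 30),
              over_30  = sum(d > 30))
  structure(list(
    n           = length(d),
    total_days  = sum(d),
    median_days = stats::median(d),
    counts      = counts,
    proportions = counts / length(d)
  ), class = "workday_summary")
}

#' @export
print.workday_summary <- function(x, ...) {
  cat(sprintf("Lost workdays over %d claims: total %s days, median %.2f days\n",
              x$n, format(x$total_days, big.mark = ","), x$median_days))
  lab <- c("<5 days", "5-30 days", ">30 days")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-9s %5d (%.1f%%)\n", lab[i], x$counts[i],
                round_half_up(100 * x$proportions[i], 1)))
  }
  invisible(x)
}

#' Frequency distribution of a categorical cohort field
#'
#' @param cohort An `injury_cohort`.
#' @param field Name of a categorical or logical column.
#' @return Data frame with `level`, `count` and `percent` (half-up, one
#'   decimal, as frequency tables are conventionally printed).
#' @export
category_distribution <- function(cohort, field) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (!field %in% names(cohort)) stop("unknown field: ", field, call. = FALSE)
  v <- cohort[[field]]
  if (is.numeric(v)) stop("`", field, "` is numeric, not categorical",
                          call. = FALSE)
  lv <- if (field %in% names(cohort_levels)) cohort_levels[[field]] else
    sort(unique(as.character(v)))
  counts <- table(factor(as.character(v), levels = lv))
  data.frame(level = names(counts),
             count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / nrow(cohort), 1),
             stringsAsFactors = FALSE)
}

#' Sample size for a single population proportion
#'
#' `ceiling(deff * z^2 * p * (1 - p) / margin^2)`: the classical single
#' population proportion formula with a design effect for multistage or
#' stratified sampling.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param margin Absolute margin of error, > 0.
#' @param z Standard-normal quantile for the confidence level (default 1.96,
#'   i.e. 95%).
#' @param deff Design effect, >= 1 (default 1).
#' @return Integer sample size.
#' @examples
#' sample_size(0.5, 0.05)                 # 385, the textbook case
#' sample_size(0.783, 0.05, deff = 1.5)   # 392
#' @export
sample_size <- function(p, margin, z = 1.96, deff = 1) {
  check_number(p, "p", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(margin, "margin", 0, strict_lower = TRUE)
  check_number(z, "z", 0, strict_lower = TRUE)
  check_number(deff, "deff", 1)
  as.integer(ceiling(deff * z^2 * p * (1 - p) / margin^2))
}
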