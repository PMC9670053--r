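# builders for small in-code cohorts; all arguments recycle to length n

make_records <- function(days,
                         wage = 200,
                         medical = 1000,
                         comp = 500,
                         disability = "temporary_total",
                         sex = "male",
                         total = NULL) {
  n <- length(days)
  df <- data.frame(
    worker_id = sprintf("W%05d", seq_len(n)),
    sex = rep_len(sex, n),
    disability_class = rep_len(disability, n),
    body_part = "hand_finger",
    cause = "machine",
    timing = "morning",
    workdays_lost = days,
    daily_wage = rep_len(wage, n),
    medical_cost = rep_len(medical, n),
    compensation = rep_len(comp, n),
    unsafe_act = 1L,
    sleeping_disorder = 0L,
    comorbidity = 0L,
    severity = "minor",
    ppe_use = "consistent",
    injury_prevents_work = 1L,
    stringsAsFactors = FALSE
  )
  if (!is.null(total)) df$total_cost <- rep_len(total, n)
  df
}

make_cohort <- function(...) {
  as_injury_cohort(make_records(...), quiet = TRUE)
}
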