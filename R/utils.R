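#' Round half away from zero
#'
#' Decimal rounding in which a digit of exactly 5 rounds away from zero,
#' matching the rendering convention of published cost tables. Base R's
#' [round()] uses banker's rounding (round-half-even), which disagrees with
#' that convention on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, i.e. cents).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(2.675, 2)   # 2.68
#' round_half_up(39.6666, 1) # 39.7
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  m <- 10^digits
  # tiny epsilon absorbs values like 2.675 that are stored just below the half
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit,
# so simulation is a pure function of (config, seed).
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# scalar argument checks ------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("`%s` must be non-negative probabilities", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}
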