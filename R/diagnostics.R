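#' @title Pre-modelling diagnostics
#' @description
#' The screening steps run before the cost GLM: collinearity via the
#' pairwise correlation matrix (flag |r| > 0.8) and variance inflation
#' factors (flag VIF > 10, tolerance < 0.1), and distributional checks on
#' the cost response — adjusted Fisher–Pearson skewness and the one-sample
#' Kolmogorov–Smirnov statistic against a normal with the sample mean and
#' SD, on the raw and log scales.
#' @name diagnostics
NULL

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of predictor `j` on all the others (plus an intercept);
#' tolerance is the reciprocal. Perfectly collinear predictors are reported
#' as `Inf` and flagged rather than erroring, so the caller sees which
#' columns to drop.
#'
#' @param x Design matrix of predictors; an `(Intercept)` column, if
#'   present, is excluded from the VIF computation.
#' @param flag_above Flag threshold (default 10).
#' @return Data frame with `predictor`, `vif`, `tolerance`, `flagged`.
#' @export
vif <- function(x, flag_above = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (ncol(x) < 2) stop("need at least two predictors", call. = FALSE)
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    others <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, xj)
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) return(NA_real_)  # constant column: undefined, not collinear
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(x),
             vif = vifs,
             tolerance = 1 / vifs,
             flagged = !is.na(vifs) & vifs > flag_above,
             stringsAsFactors = FALSE)
}

#' Pairwise-correlation collinearity screen
#'
#' @param x Design matrix of predictors (intercept column ignored).
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.8).
#' @return List with `max_abs_correlation` and `flags` (data frame of
#'   flagged pairs and their correlation).
#' @export
correlation_screen <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (ncol(x) < 2) stop("need at least two predictors", call. = FALSE)
  r <- stats::cor(x)
  off <- r
  diag(off) <- 0
  idx <- which(abs(off) > threshold & upper.tri(off), arr.ind = TRUE)
  list(max_abs_correlation = max(abs(off)),
       flags = data.frame(var1 = colnames(x)[idx[, 1]],
                          var2 = colnames(x)[idx[, 2]],
                          r = off[idx],
                          stringsAsFactors = FALSE))
}

# adjusted Fisher-Pearson sample skewness: g1 * sqrt(n(n-1))/(n-2) with the
# sample (n-1) standard deviation in the denominator
.skewness <- function(y) {
  n <- length(y)
  m <- mean(y)
  s <- stats::sd(y)
  if (s == 0) return(0)
  (n^2 / ((n - 1) * (n - 2))) * sum((y - m)^3) / n / s^3
}

#' Normality check of a cost distribution
#'
#' Reports the adjusted Fisher–Pearson skewness and the one-sample
#' Kolmogorov–Smirnov statistic D (against a normal with the sample mean and
#' SD) for the raw values, and — when `log_transform` — for their
#' logarithms, together with whether the log scale looks normal at the 0.05
#' level. Cost data are typically strongly right-skewed on the raw scale,
#' which is what motivates the gamma/log model.
#'
#' @param y Numeric vector, `length(y) >= 8`.
#' @param log_transform Also check `log(y)` (default `TRUE`; requires all
#'   `y > 0`).
#' @param alpha Significance level for the KS decision (default 0.05).
#' @return A `normality_report` list: `n`, `skewness_raw`, `ks_raw`,
#'   `p_raw`, and when requested `skewness_log`, `ks_log`, `p_log`,
#'   `normal_after_log`.
#' @export
normality_check <- function(y, log_transform = TRUE, alpha = 0.05) {
  y <- as.numeric(y)
  if (length(y) < 8 || anyNA(y)) {
    stop("need at least 8 non-missing values", call. = FALSE)
  }
  ks <- function(v) {
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
  }
  k_raw <- ks(y)
  out <- list(n = length(y),
              skewness_raw = .skewness(y),
              ks_raw = unname(k_raw$statistic),
              p_raw = k_raw$p.value)
  if (log_transform) {
    if (any(y <= 0)) {
      stop("log transform requested but response has values <= 0",
           call. = FALSE)
    }
    ly <- log(y)
    k_log <- ks(ly)
    out$skewness_log <- .skewness(ly)
    out$ks_log <- unname(k_log$statistic)
    out$p_log <- k_log$p.value
    out$normal_after_log <- k_log$p.value > alpha
  }
  structure(out, class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("Normality check (n = %d)\n", x$n))
  cat(sprintf("  raw: skewness %.3f, KS D %.4f (p %.3g)\n",
              x$skewness_raw, x$ks_raw, x$p_raw))
  if (!is.null(x$ks_log)) {
    cat(sprintf("  log: skewness %.3f, KS D %.4f (p %.3g) -> %snormal at log scale\n",
                x$skewness_log, x$ks_log, x$p_log,
                if (x$normal_after_log) "" else "not "))
  }
  invisible(x)
}

#' Combined pre-modelling diagnostics report
#'
#' @param x Design matrix of predictors (as for [vif()]).
#' @param y Positive cost response.
#' @return A `diagnostics_report` list bundling [vif()],
#'   [correlation_screen()] and [normality_check()] results.
#' @export
diagnostics_report <- function(x, y) {
  structure(list(vif = vif(x),
                 correlation = correlation_screen(x),
                 normality = normality_check(y)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Collinearity:\n")
  print(x$vif)
  cat(sprintf("max |r| = %.3f; %d pair(s) above 0.8\n",
              x$correlation$max_abs_correlation, nrow(x$correlation$flags)))
  print(x$normality)
  invisible(x)
}
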