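#' @title Gamma log-link GLM for cost predictors
#' @description
#' Per-claim total cost is positive and right-skewed, so predictors of cost
#' are modelled with a gamma-family generalized linear model with log link:
#' `log E[y_i] = x_i' b`. The fit is by iteratively reweighted least squares
#' (IRLS). For the log link the gamma working weights are identically 1
#' (`(dmu/deta)^2 / V(mu) = mu^2 / mu^2`), so each iteration is an ordinary
#' least-squares solve of the working response `eta + (y - mu)/mu` on the
#' design. Exponentiated coefficients `exp(b)` are multiplicative effects on
#' mean cost (not odds ratios — a gamma/log model has no odds scale), with
#' Wald 95% intervals `exp(b +/- 1.96 se)` computed on the log scale.
#' Standard errors come from the inverse Fisher information scaled by the
#' Pearson estimate of dispersion.
#' @name gamma-glm
NULL

.z975 <- 1.959964

#' Build a 0/1 design matrix from a cohort
#'
#' @param cohort An `injury_cohort`.
#' @param predictors Character vector of predictor names; each must be a
#'   logical column, a 0/1 column, or one of the two-level codings
#'   `severity` (severe = 1) / `ppe_use` (inconsistent = 1). The alias
#'   `ppe_inconsistent` is accepted for `ppe_use`.
#' @return Numeric matrix with an `(Intercept)` column followed by one 0/1
#'   column per predictor.
#' @export
design_matrix <- function(cohort,
                          predictors = c("long_term_absence", "severity",
                                         "unsafe_act", "sleeping_disorder",
                                         "comorbidity", "ppe_inconsistent")) {
  stopifnot(inherits(cohort, "injury_cohort"))
  cols <- lapply(predictors, function(p) {
    if (p == "severity") return(as.numeric(cohort$severity == "severe"))
    if (p %in% c("ppe_use", "ppe_inconsistent")) {
      return(as.numeric(cohort$ppe_use == "inconsistent"))
    }
    if (!p %in% names(cohort)) stop("unknown predictor: ", p, call. = FALSE)
    v <- cohort[[p]]
    if (is.logical(v)) return(as.numeric(v))
    if (is.numeric(v) && all(v %in% c(0, 1))) return(v)
    stop("predictor `", p, "` is not binary", call. = FALSE)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- predictors
  cbind(`(Intercept)` = 1, x)
}

# ensure a design matrix with a leading intercept column
.with_intercept <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (!"(Intercept)" %in% colnames(x)) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  x
}

# gamma deviance, shape-free (scaled by the dispersion outside)
.gamma_deviance <- function(y, mu) 2 * sum((y - mu) / mu - log(y / mu))

#' Fit a gamma GLM with log link by IRLS
#'
#' @param x Design matrix (an intercept column named `"(Intercept)"` is
#'   prepended when absent), e.g. from [design_matrix()].
#' @param y Positive response vector (per-claim total cost, ETB).
#' @param tol Convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A `gamma_glm` list: `coefficients` (log scale), `exp_b`, `se`,
#'   `ci95` (matrix of exp-scale lower/upper bounds), `fitted`, `deviance`,
#'   `pearson`, `dispersion` (Pearson chi-square / (n - p)), `converged`,
#'   `n_iterations`, `df_residual`. Non-convergence is reported in the
#'   object and by a warning, never silently.
#' @examples
#' fit <- fit_gamma_log_glm(matrix(nrow = 3, ncol = 0), c(1, 2, 3))
#' exp(fit$coefficients) # 2, the sample mean
#' @export
fit_gamma_log_glm <- function(x, y, tol = 1e-8, max_iter = 100L) {
  x <- .with_intercept(x)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(x)
  if (nrow(x) != n) stop("nrow(x) != length(y)", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response",
                                 call. = FALSE)
  if (any(y <= 0)) {
    stop("gamma response must be strictly positive (", sum(y <= 0),
         " value(s) <= 0)", call. = FALSE)
  }
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  qx <- qr(x)
  if (qx$rank < p) stop("design matrix is rank-deficient", call. = FALSE)

  # start from OLS on log(y)
  b <- qr.coef(qx, log(y))
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% b)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    b <- qr.coef(qx, z)
    mu_new <- exp(drop(x %*% b))
    dev_new <- .gamma_deviance(y, mu_new)
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("IRLS did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  mu <- exp(drop(x %*% b))
  pearson <- sum(((y - mu) / mu)^2)
  dispersion <- pearson / (n - p)
  # Fisher information for gamma/log is X'X / dispersion (unit weights)
  cov_b <- chol2inv(qr.R(qx)) * dispersion
  se <- sqrt(diag(cov_b))
  names(se) <- colnames(x)
  ci <- cbind(lower = exp(b - .z975 * se), upper = exp(b + .z975 * se))
  structure(list(coefficients = b, exp_b = exp(b), se = se, ci95 = ci,
                 fitted = mu, deviance = dev, pearson = pearson,
                 dispersion = dispersion, converged = converged,
                 n_iterations = iter, df_residual = n - p, n = n),
            class = "gamma_glm")
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf(
    "Gamma GLM (log link), n = %d, %s in %d IRLS iteration(s)\n", x$n,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  tab <- data.frame(b = x$coefficients, exp_b = x$exp_b, se = x$se,
                    ci_low = x$ci95[, "lower"], ci_high = x$ci95[, "upper"])
  print(round(tab, 4))
  cat(sprintf("Residual deviance %.4f on %d df; Pearson dispersion %.4f\n",
              x$deviance, x$df_residual, x$dispersion))
  invisible(x)
}

#' Exponentiated-coefficient table
#'
#' One row per non-intercept predictor with the multiplicative cost ratio
#' `exp(b)`, its log-scale standard error, and the Wald 95% interval on the
#' exp scale. Values are full precision; the print method displays two
#' decimals as such tables are conventionally reported.
#'
#' @param fit A converged [fit_gamma_log_glm()] result.
#' @return Data frame of class `exp_coef_table` with columns `predictor`,
#'   `exp_b`, `se`, `ci_low`, `ci_high`.
#' @export
exp_coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "gamma_glm"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to tabulate coefficients",
         call. = FALSE)
  }
  keep <- names(fit$coefficients) != "(Intercept)"
  out <- data.frame(predictor = names(fit$coefficients)[keep],
                    exp_b = unname(fit$exp_b[keep]),
                    se = unname(fit$se[keep]),
                    ci_low = unname(fit$ci95[keep, "lower"]),
                    ci_high = unname(fit$ci95[keep, "upper"]),
                    stringsAsFactors = FALSE)
  class(out) <- c("exp_coef_table", "data.frame")
  out
}

#' @export
print.exp_coef_table <- function(x, ...) {
  disp <- x
  for (col in c("exp_b", "se", "ci_low", "ci_high")) {
    disp[[col]] <- sprintf("%.2f", round_half_up(x[[col]], 2))
  }
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}
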