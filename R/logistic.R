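# Univariate association analyses: logistic odds ratios with Wald
# confidence intervals, Welch/pooled t-tests and Fisher's exact test. The
# model fits delegate to the standard IRLS machinery in stats::glm.

#' Univariate logistic regression of a binary outcome on one covariate
#'
#' Maximum-likelihood fit (iteratively reweighted least squares, tolerance
#' `1e-8`, at most 25 iterations) of `y ~ x`, returning the slope, its odds
#' ratio `exp(beta)` with Wald 95% confidence interval, and the Wald
#' p-value. Complete separation is reported as an error naming the
#' covariate.
#'
#' @param y binary outcome (logical or 0/1).
#' @param x numeric or binary covariate.
#' @param name covariate name for messages and reports.
#' @param conf_level confidence level.
#' @return Object of class `logistic_fit`: `beta`, `intercept`, `se`,
#'   `odds_ratio`, `ci_95` (on the odds-ratio scale), `p_value`, `name`,
#'   `n`.
#' @export
univariate_logistic <- function(y, x, name = deparse(substitute(x)),
                                conf_level = 0.95) {
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(x)) stop("no missing values allowed")
  if (length(unique(y)) < 2L) stop("'y' must contain both classes")
  if (length(unique(x)) < 2L)
    stop(sprintf("covariate '%s' is constant", name))
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)))
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  mu <- fit$fitted.values
  if (!fit$converged || abs(beta) > 50 ||
      (all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8)))
    stop(sprintf("logistic fit did not converge for covariate '%s' (separation?)",
                 name))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = beta, intercept = co["(Intercept)", "Estimate"],
                 se = se, odds_ratio = exp(beta),
                 ci_95 = exp(beta + c(-1, 1) * z * se),
                 p_value = co["x", "Pr(>|z|)"], name = name,
                 n = length(y)), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> %s: beta %.4f (SE %.4f), OR %.3f (%.3f-%.3f), p = %.3g\n",
    x$name, x$beta, x$se, x$odds_ratio, x$ci_95[1], x$ci_95[2], x$p_value))
  invisible(x)
}

#' Odds ratio and percent change from a logistic slope
#'
#' For a one-unit increase of the covariate the odds multiply by
#' `exp(beta)`; the corresponding percent change is `100 * (exp(beta) - 1)`.
#'
#' @param beta finite logistic slope.
#' @return list with `odds_ratio` and `pct_change`.
#' @export
or_from_beta <- function(beta) {
  stopifnot_scalar(beta, "beta")
  list(odds_ratio = exp(beta), pct_change = 100 * (exp(beta) - 1))
}

#' Two-sample t-test (Welch by default)
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both groups are constant; t-test undefined")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration (tables with
#' probability less than or equal to the observed one).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != round(table)))
    stop("'table' must be a 2x2 matrix of non-negative integer counts")
  stats::fisher.test(table)$p.value
}
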