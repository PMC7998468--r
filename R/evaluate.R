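# Cohort-level evaluation: per-method diagnostic performance at the
# Youden-optimal cutoff, and the univariate factor analysis of
# correct/incorrect classification.

#' Diagnostic performance of all four measurement methods
#'
#' Restricted to patients measured successfully by all four methods (rows
#' with no missing translation), computes per method the empirical ROC and
#' AUC, the Youden-optimal cutoff, and the full 2x2 diagnostic performance
#' at that cutoff (positive call: translation >= cutoff).
#'
#' @param cohort data.frame with columns `acl_torn` and `m1`..`m4`
#'   (translation, mm; `NA` = failed measurement).
#' @param conf_level confidence level for the Wald intervals.
#' @param ci_denominator passed to [diag_performance()].
#' @return Object of class `method_evaluation`: `table` (one row per
#'   method: auc, cutoff, j, counts and the five metrics with CIs), `rocs`,
#'   `performance` (list of [diag_performance()]), `n_used`, `n_dropped`.
#' @export
evaluate_methods <- function(cohort, conf_level = 0.95,
                             ci_denominator = "total") {
  need <- c("acl_torn", paste0("m", 1:4))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("cohort is missing column(s): %s", paste(miss, collapse = ", ")))
  if (!nrow(cohort)) stop("empty cohort")
  ok <- stats::complete.cases(cohort[, need])
  d <- cohort[ok, , drop = FALSE]
  if (!nrow(d)) stop("no patient has successful measurements by all methods")
  if (length(unique(d$acl_torn)) < 2L)
    stop("cohort must contain both torn and intact cases")
  rocs <- list(); perf <- list(); rows <- list()
  for (m in 1:4) {
    scores <- d[[paste0("m", m)]]
    roc <- roc_curve(scores, d$acl_torn)
    cut <- youden_cutoff(roc)
    call_pos <- scores >= cut$threshold
    tp <- sum(call_pos & d$acl_torn == 1)
    fn <- sum(!call_pos & d$acl_torn == 1)
    fp <- sum(call_pos & d$acl_torn == 0)
    tn <- sum(!call_pos & d$acl_torn == 0)
    dp <- diag_performance(tp, fn, fp, tn, conf_level = conf_level,
                           ci_denominator = ci_denominator)
    met <- dp$metrics
    row <- data.frame(method = m, auc = roc$auc, cutoff_mm = cut$threshold,
                      youden_j = cut$j_statistic,
                      tp = tp, fn = fn, fp = fp, tn = tn)
    for (i in seq_len(nrow(met))) {
      row[[met$metric[i]]] <- met$estimate[i]
      row[[paste0(met$metric[i], "_lo")]] <- met$lo[i]
      row[[paste0(met$metric[i], "_hi")]] <- met$hi[i]
    }
    rows[[m]] <- row; rocs[[m]] <- roc; perf[[m]] <- dp
  }
  structure(list(table = do.call(rbind, rows), rocs = rocs,
                 performance = perf, n_used = nrow(d),
                 n_dropped = sum(!ok)), class = "method_evaluation")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("<method_evaluation> %d patients (%d dropped for any failed method)\n",
              x$n_used, x$n_dropped))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf(
      "  method %d: AUC %.3f, cutoff %.2f mm, sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
      t$method[i], t$auc[i], t$cutoff_mm[i], 100 * t$sensitivity[i],
      100 * t$specificity[i], 100 * t$accuracy[i]))
  invisible(x)
}

#' Univariate factor analysis of diagnostic accuracy
#'
#' For each covariate, compares accurate versus error cases (mean +/- SD for
#' continuous covariates, counts for binary ones), fits the univariate
#' logistic regression of the correct/incorrect flag, and computes the
#' group-comparison p-value (Welch or pooled t-test for continuous,
#' Fisher's exact test for binary covariates).
#'
#' @param cohort data.frame with a binary `correct` column and the covariate
#'   columns.
#' @param covariates character vector of covariate column names; the
#'   default is the full technical/clinical set.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame, one row per covariate: group summaries, `odds_ratio`
#'   with CI, `beta`, `p_value`.
#' @export
accuracy_factor_analysis <- function(
    cohort,
    covariates = c("age", "male", "interval_d", "flexion_deg",
                   "intercondylar_mm", "fj_dist_mm", "fj_angle_deg"),
    var_equal = FALSE) {
  if (!"correct" %in% names(cohort))
    stop("cohort needs a binary 'correct' column")
  y <- cohort$correct
  rows <- list()
  for (v in covariates) {
    if (!v %in% names(cohort) || all(is.na(cohort[[v]]))) {
      warning(sprintf("covariate '%s' missing; skipped", v))
      next
    }
    x <- cohort[[v]]
    binary <- length(unique(x)) <= 2L
    fit <- univariate_logistic(y, x, name = v)
    if (binary) {
      tab <- table(factor(x, levels = sort(unique(x), decreasing = TRUE)),
                   factor(y, levels = c(1, 0)))
      p <- fisher_exact(tab)
      acc_sum <- sprintf("%d (%.2f%%)", sum(x == max(x) & y == 1),
                         100 * mean(x[y == 1] == max(x)))
      err_sum <- sprintf("%d (%.2f%%)", sum(x == max(x) & y == 0),
                         100 * mean(x[y == 0] == max(x)))
    } else {
      p <- two_sample_t(x[y == 1], x[y == 0], var_equal = var_equal)$p
      acc_sum <- sprintf("%.2f +/- %.2f", mean(x[y == 1]), stats::sd(x[y == 1]))
      err_sum <- sprintf("%.2f +/- %.2f", mean(x[y == 0]), stats::sd(x[y == 0]))
    }
    rows[[v]] <- data.frame(
      covariate = v, type = if (binary) "binary" else "continuous",
      accurate = acc_sum, error = err_sum,
      odds_ratio = fit$odds_ratio, or_lo = fit$ci_95[1],
      or_hi = fit$ci_95[2], beta = fit$beta, p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
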