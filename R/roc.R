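# Empirical ROC analysis for the translation measurements. Positive-call
# convention throughout: a case is called torn when its score (translation,
# mm) is >= the threshold — larger anterior translation means a more likely
# complete tear.

#' Empirical ROC curve and trapezoid AUC
#'
#' Computes sensitivity and specificity at every distinct score threshold
#' (positive call when `score >= threshold`) and the area under the curve by
#' the trapezoid rule, which for the empirical ROC equals the Mann--Whitney
#' estimator `P(score_pos > score_neg) + P(equal)/2`.
#'
#' @param scores numeric scores (e.g. translation in mm).
#' @param labels binary truth (logical, or 0/1), `TRUE`/1 = diseased.
#' @return An object of class `roc_result`: `thresholds` (ascending),
#'   `sensitivity`, `specificity` (aligned), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("'scores' and 'labels' must be same length and free of NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  # trapezoid over (FPR, TPR) swept from the most lenient to strictest call
  fpr <- c(1, 1 - spec, 0)                 # thresholds ascending
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d diseased / %d non-diseased, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(c(1, 1 - x$specificity, 0), c(1, x$sensitivity, 0),
                 type = "l", xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The threshold maximizing Youden's `J = sensitivity + specificity - 1`;
#' ties are broken toward the lowest threshold (maximizing sensitivity).
#'
#' @param roc a [roc_curve()] result.
#' @return list with `threshold`, `j_statistic`, `sensitivity`,
#'   `specificity` at the cutoff.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which.max(j)                       # first max = lowest threshold
  list(threshold = roc$thresholds[i], j_statistic = j[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
}

#' Diagnostic performance from a 2x2 confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy with Wald 95% confidence intervals. By default the Wald standard
#' error uses the total sample size as denominator, the convention that
#' reproduces the published reference intervals for this system;
#' `ci_denominator = "metric"` uses each metric's own denominator instead.
#' Metrics with a zero denominator are returned as `NA` and flagged.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param conf_level confidence level (default 0.95).
#' @param ci_denominator `"total"` or `"metric"`.
#' @return Object of class `diag_performance`: a data.frame `metrics` with
#'   columns `metric`, `num`, `den`, `estimate`, `lo`, `hi`, `undefined`,
#'   plus the counts.
#' @export
diag_performance <- function(tp, fn, fp, tn, conf_level = 0.95,
                             ci_denominator = c("total", "metric")) {
  ci_denominator <- match.arg(ci_denominator)
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  defs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv         = c(tp, tp + fp),
    npv         = c(tn, tn + fn),
    accuracy    = c(tp + tn, n))
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]; den <- defs[[m]][2]
    if (den == 0)
      return(data.frame(metric = m, num = num, den = den,
                        estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                        undefined = TRUE))
    p <- num / den
    nd <- if (ci_denominator == "total") n else den
    se <- sqrt(p * (1 - p) / nd)
    data.frame(metric = m, num = num, den = den, estimate = p,
               lo = max(0, p - z * se), hi = min(1, p + z * se),
               undefined = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows),
                 counts = counts, conf_level = conf_level,
                 ci_denominator = ci_denominator),
            class = "diag_performance")
}

#' @export
print.diag_performance <- function(x, digits = 1, ...) {
  cat(sprintf("<diag_performance> tp=%d fn=%d fp=%d tn=%d\n",
              x$counts["tp"], x$counts["fn"], x$counts["fp"], x$counts["tn"]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$undefined[i]) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %d/%d, %.*f%% (%.*f-%.*f)\n", m$metric[i],
                  m$num[i], m$den[i], digits, 100 * m$estimate[i],
                  digits, 100 * m$lo[i], digits, 100 * m$hi[i]))
    }
  }
  invisible(x)
}

#' Sample size for detecting an AUC above a null value
#'
#' Smallest per-group `n` satisfying the Hanley--McNeil normal-approximation
#' power condition for a one-ROC comparison against a null AUC, with
#' variance `V(A) = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)`,
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, two-sided alpha. The exact formula
#' behind any particular published sample size depends on software choices;
#' this implementation documents its own.
#'
#' @param auc_alt alternative-hypothesis AUC (`auc_null < auc_alt < 1`).
#' @param auc_null null AUC (default 0.5).
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param ratio allocation ratio `n2 / n1`.
#' @return Integer `n` per (first) group.
#' @export
auc_sample_size <- function(auc_alt, auc_null = 0.5, alpha = 0.05,
                            power = 0.8, ratio = 1) {
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    stop("need 0.5 <= auc_null < auc_alt < 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  v <- function(a, n1, n2) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) / (n1 * n2)
  }
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(power)
  for (n in 2:1000000) {
    n2 <- ceiling(ratio * n)
    lhs <- za * sqrt(v(auc_null, n, n2)) + zb * sqrt(v(auc_alt, n, n2))
    if (lhs <= auc_alt - auc_null) return(n)
  }
  stop("no feasible sample size below 1e6; parameters too close")
}
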