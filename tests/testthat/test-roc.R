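# Empirical ROC, Youden cutoff, diagnostic performance, sample size.

test_that("AUC is 1 for separated scores and ~0.5 under independence", {
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  # pair-counting oracle on a fully separated toy vector
  expect_equal(roc_curve(1:4, c(0, 0, 1, 1))$auc,
               auc_pair_count(1:4, c(0, 0, 1, 1)))
  set.seed(14)
  s <- rnorm(6000); y <- rbinom(6000, 1, 0.4)
  expect_equal(roc_curve(s, y)$auc, 0.5, tolerance = 0.02)
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney pair count, ties included", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- sample(1:8, n, replace = TRUE)        # heavy ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    roc <- roc_curve(s, y)
    expect_equal(roc$auc, auc_pair_count(s, y), tolerance = 1e-12)
    # monotone invariants of the empirical curve
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(8)
  s <- c(rnorm(60, 1), rnorm(40)); y <- rep(c(1, 0), c(60, 40))
  a_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
  expect_equal(roc_curve(s, y)$auc, a_ref, tolerance = 1e-12)
})

test_that("Youden cutoff equals a brute-force scan with low-threshold ties", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    s <- round(rnorm(n, ifelse(rbinom(n, 1, 0.6) == 1, 1, 0), 1.2), 1)
    y <- rbinom(n, 1, 0.55)
    if (length(unique(y)) < 2) next
    roc <- roc_curve(s, y)
    cut <- youden_cutoff(roc)
    expect_equal(cut$threshold, youden_scan(s, y))
    expect_equal(cut$j_statistic,
                 cut$sensitivity + cut$specificity - 1, tolerance = 1e-12)
  }
  # all-equal J -> lowest threshold wins
  roc1 <- roc_curve(c(1, 2), c(0, 1))
  expect_equal(youden_cutoff(roc1)$threshold, 2)   # unique maximum
})

test_that("diagnostic metrics satisfy their defining identities", {
  set.seed(6)
  for (i in 1:25) {
    cnt <- rpois(4, 30)
    if (any(cnt[c(1, 2)] == 0) || any(cnt[c(3, 4)] == 0)) next
    dp <- diag_performance(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- dp$metrics; est <- setNames(m$estimate, m$metric)
    tp <- cnt[1]; fn <- cnt[2]; fp <- cnt[3]; tn <- cnt[4]
    expect_equal(est[["sensitivity"]], tp / (tp + fn))
    expect_equal(est[["specificity"]], tn / (tn + fp))
    expect_equal(est[["ppv"]], tp / (tp + fp))
    expect_equal(est[["npv"]], tn / (tn + fn))
    expect_equal(est[["accuracy"]], (tp + tn) / sum(cnt))
    # accuracy = prevalence * sens + (1 - prevalence) * spec, exactly
    prev <- (tp + fn) / sum(cnt)
    expect_equal(est[["accuracy"]],
                 prev * est[["sensitivity"]] + (1 - prev) * est[["specificity"]],
                 tolerance = 1e-12)
    expect_true(all(m$lo <= m$estimate & m$estimate <= m$hi))
  }
})

test_that("zero denominators are flagged undefined, not computed", {
  dp <- diag_performance(10, 0, 0, 0)
  m <- dp$metrics
  expect_equal(m$estimate[m$metric == "sensitivity"], 1)
  expect_true(m$undefined[m$metric == "specificity"])
  expect_true(is.na(m$estimate[m$metric == "specificity"]))
  expect_error(diag_performance(-1, 2, 3, 4), "non-negative")
})

test_that("metric-denominator intervals widen for the smaller subgroups", {
  dp_tot <- diag_performance(106, 23, 21, 27, ci_denominator = "total")
  dp_met <- diag_performance(106, 23, 21, 27, ci_denominator = "metric")
  w <- function(dp, metric) {
    m <- dp$metrics; m$hi[m$metric == metric] - m$lo[m$metric == metric]
  }
  # specificity rests on 48 cases: its own-denominator interval is wider
  expect_gt(w(dp_met, "specificity"), w(dp_tot, "specificity"))
  expect_equal(w(dp_met, "accuracy"), w(dp_tot, "accuracy"))
})

test_that("AUC sample size is monotone and diverges near the null", {
  n_list <- vapply(c(0.55, 0.6, 0.7, 0.8, 0.9), function(a)
    auc_sample_size(a), numeric(1))
  expect_true(all(diff(n_list) < 0))             # larger effect, smaller n
  expect_gt(auc_sample_size(0.52), auc_sample_size(0.6))
  expect_error(auc_sample_size(0.5), "auc_null")
  expect_error(auc_sample_size(0.8, alpha = 0), "alpha")
})
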