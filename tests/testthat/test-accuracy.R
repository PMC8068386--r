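test_that("confusion table at a threshold respects orientation and boundaries", {
  cohort <- table3_cohort()
  s <- score_patient(cohort$peak_vo2, cohort$ve_vco2_slope,
                     cohort$petco2_basal)
  tab <- confusion_at_threshold(s, cohort$group == "CTD_PAH", 3,
                                "higher_is_diseased")
  expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(7L, 1L, 1L, 111L))

  v <- c(1, 2, 3)
  d <- c(TRUE, FALSE, TRUE)
  all_pos <- confusion_at_threshold(v, d, 10, "lower_is_diseased")
  expect_identical(c(all_pos$fn, all_pos$tn), c(0L, 0L))
  none_pos <- confusion_at_threshold(v, d, 0.5, "lower_is_diseased")
  expect_identical(c(none_pos$tp, none_pos$fp), c(0L, 0L))

  # strict flag controls positivity at the cutoff itself
  at <- confusion_at_threshold(c(5, 5), c(TRUE, FALSE), 5,
                               "higher_is_diseased")
  expect_identical(at$tp, 1L)
  at_strict <- confusion_at_threshold(c(5, 5), c(TRUE, FALSE), 5,
                                      "higher_is_diseased", strict = TRUE)
  expect_identical(at_strict$tp, 0L)

  expect_error(confusion_at_threshold(1:3, c(TRUE, FALSE), 2), "length")
  expect_error(confusion_at_threshold(1:3, c(TRUE, TRUE, TRUE), 2), "both")
})

test_that("exact binomial intervals reproduce published bounds and agree with binom.test", {
  ci <- clopper_pearson(7, 8)
  expect_equal(round(100 * ci, 1), c(lower = 47.3, upper = 99.7))
  ci2 <- clopper_pearson(111, 112)
  expect_equal(round(100 * ci2, 1), c(lower = 95.1, upper = 100.0))
  expect_identical(clopper_pearson(0, 10)[["lower"]], 0)
  expect_identical(clopper_pearson(10, 10)[["upper"]], 1)
  # independent oracle across a grid
  for (x in c(0, 1, 4, 9, 10)) {
    bt <- binom.test(x, 10)$conf.int
    expect_equal(unname(clopper_pearson(x, 10)), as.numeric(bt),
                 tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 4), "counts")
})

test_that("likelihood ratios and log-method intervals match the 2x2 arithmetic", {
  lr <- likelihood_ratios(two_by_two(7, 1, 1, 111))
  expect_equal(lr$lr_pos[["estimate"]], 98, tolerance = 1e-12)
  expect_equal(round(lr$lr_neg[["estimate"]], 2), 0.13)
  expect_equal(lr$lr_pos[["lower"]], 13.7, tolerance = 0.01)
  expect_equal(lr$lr_pos[["upper"]], 701.8, tolerance = 0.001)
  expect_equal(round(lr$lr_neg[["lower"]], 2), 0.02)
  expect_equal(round(lr$lr_neg[["upper"]], 1), 0.8)

  # uninformative test
  lr5 <- likelihood_ratios(two_by_two(5, 5, 5, 5))
  expect_equal(lr5$lr_pos[["estimate"]], 1)
  expect_equal(lr5$lr_neg[["estimate"]], 1)

  # perfect test: signalled infinity and zero, undefined intervals
  lrp <- likelihood_ratios(two_by_two(8, 0, 0, 112))
  expect_identical(lrp$lr_pos[["estimate"]], Inf)
  expect_identical(lrp$lr_neg[["estimate"]], 0)
  expect_true(is.na(lrp$lr_pos[["lower"]]))
  # Haldane-Anscombe correction makes them finite
  lrc <- likelihood_ratios(two_by_two(8, 0, 0, 112), correction = TRUE)
  expect_true(is.finite(lrc$lr_pos[["estimate"]]))
})

test_that("Bayes predictive values reproduce the 10%-prevalence panel", {
  lr <- likelihood_ratios(two_by_two(7, 1, 1, 111))
  pv <- predictive_values(7 / 8, 111 / 112, 0.10, lr)
  expect_equal(round(100 * pv$ppv[["estimate"]], 1), 91.6)
  expect_equal(round(100 * pv$npv[["estimate"]], 1), 98.6)
  expect_equal(round(100 * pv$ppv[["lower"]], 1), 60.3)
  expect_equal(round(100 * pv$ppv[["upper"]], 1), 98.7)
  expect_equal(round(100 * pv$npv[["lower"]], 1), 91.9)
  expect_equal(round(100 * pv$npv[["upper"]], 1), 99.8)

  perfect <- predictive_values(1, 1, 0.37)
  expect_equal(perfect$ppv[["estimate"]], 1)
  expect_equal(perfect$npv[["estimate"]], 1)

  tiny <- predictive_values(7 / 8, 111 / 112, 1e-8)
  expect_lt(tiny$ppv[["estimate"]], 1e-5)
  expect_gt(tiny$npv[["estimate"]], 1 - 1e-7)
  expect_error(predictive_values(0.9, 0.9, 0), "prevalence")
  expect_error(predictive_values(0.9, 0.9, 1), "prevalence")
})

test_that("predictive values at the sample prevalence equal the raw 2x2 ratios", {
  set.seed(17)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    tp <- cnt[1]; fp <- cnt[2]; fn <- cnt[3]; tn <- cnt[4]
    if (tp + fn == 0 || fp + tn == 0 || tp + fp == 0 || tn + fn == 0) next
    if (fp == 0 || tn == 0) next  # keep LRs finite and nonzero
    prev <- (tp + fn) / sum(cnt)
    if (prev <= 0 || prev >= 1) next
    pv <- predictive_values(tp / (tp + fn), tn / (fp + tn), prev)
    expect_equal(pv$ppv[["estimate"]], tp / (tp + fp), tolerance = 1e-12)
    expect_equal(pv$npv[["estimate"]], tn / (tn + fn), tolerance = 1e-12)
  }
})

test_that("empirical ROC curve is monotone with full-range endpoints", {
  set.seed(23)
  for (orient in c("lower_is_diseased", "higher_is_diseased")) {
    v <- round(rnorm(40, 10, 3), 1)
    d <- rbinom(40, 1, 0.3) == 1
    if (!any(d) || all(d)) next
    curve <- roc_curve(v, d, orient)
    # tightening the positivity criterion never raises sensitivity
    s <- if (orient == "lower_is_diseased") rev(curve$sensitivity)
         else curve$sensitivity
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(max(curve$sensitivity), 1)
    expect_equal(min(curve$sensitivity), 0)
  }
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "both classes")
  expect_error(roc_curve(c(2, 2), c(TRUE, FALSE)), "distinct")
})

test_that("AUC equals exhaustive pairwise counting and flips with orientation", {
  # fixed example: diseased {1,2,4}, healthy {3,5}
  v <- c(1, 2, 4, 3, 5)
  d <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  curve <- roc_curve(v, d, "higher_is_diseased")
  expect_equal(auc(curve), auc_pairwise(v, d, "higher_is_diseased"))
  expect_equal(auc(curve), 1 / 6)

  set.seed(29)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    v <- sample(1:12, n, replace = TRUE)  # plenty of ties
    d <- rbinom(n, 1, 0.4) == 1
    if (!any(d) || all(d) || length(unique(v)) < 2) next
    hi <- roc_curve(v, d, "higher_is_diseased")
    lo <- roc_curve(v, d, "lower_is_diseased")
    expect_equal(auc(hi), auc_pairwise(v, d, "higher_is_diseased"))
    expect_equal(auc(lo), 1 - auc(hi))
  }

  # degenerate situations
  sep <- roc_curve(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE),
                   "higher_is_diseased")
  expect_equal(auc(sep), 1)
  near_tie <- roc_curve(c(7, 7, 7, 8), c(TRUE, FALSE, TRUE, FALSE),
                        "higher_is_diseased")
  expect_equal(auc(near_tie), auc_pairwise(c(7, 7, 7, 8),
                                           c(TRUE, FALSE, TRUE, FALSE),
                                           "higher_is_diseased"))
})

test_that("DeLong interval contains the point estimate and matches pROC", {
  set.seed(31)
  v <- c(rnorm(60, 10, 2), rnorm(25, 13, 2))
  d <- rep(c(FALSE, TRUE), c(60, 25))
  curve <- roc_curve(v, d, "higher_is_diseased")
  ci <- auc_ci(curve)
  expect_true(ci[["lower"]] <= ci[["auc"]] && ci[["auc"]] <= ci[["upper"]])
  expect_equal(ci[["auc"]], auc(curve))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = d, predictor = v, direction = "<",
                  levels = c(FALSE, TRUE), quiet = TRUE)
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(unname(ci), pci[c(2, 1, 3)], tolerance = 1e-9)
})

test_that("Youden selection agrees with an exhaustive threshold scan", {
  # worked example: diseased {1,2,4}, healthy {3,5}, low values diseased
  v <- c(1, 2, 4, 3, 5)
  d <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  curve <- roc_curve(v, d, "lower_is_diseased")
  opt <- youden_optimal(curve)
  expect_equal(opt$J, youden_scan(v, d, "lower_is_diseased"))

  set.seed(37)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    v <- sample(seq(0, 20, 0.5), n, replace = TRUE)
    d <- rbinom(n, 1, 0.35) == 1
    if (!any(d) || all(d) || length(unique(v)) < 2) next
    orient <- sample(c("lower_is_diseased", "higher_is_diseased"), 1)
    curve <- roc_curve(v, d, orient)
    opt <- youden_optimal(curve)
    expect_equal(opt$J, youden_scan(v, d, orient))
    expect_equal(opt$J, opt$sensitivity + opt$specificity - 1)
  }

  # perfectly separated classes reach J = 1
  sep <- roc_curve(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE),
                   "lower_is_diseased")
  expect_equal(youden_optimal(sep)$J, 1)
})

test_that("accuracy report invariants hold on random tables", {
  set.seed(41)
  for (i in 1:40) {
    tab <- two_by_two(sample(1:30, 1), sample(1:30, 1), sample(1:30, 1),
                      sample(1:30, 1))
    rep <- accuracy_report(tab, prevalence = runif(1, 0.02, 0.5))
    for (m in c("sensitivity", "specificity", "ppv", "npv")) {
      v <- rep[[m]]
      expect_true(v[["lower"]] <= v[["estimate"]] + 1e-12)
      expect_true(v[["estimate"]] <= v[["upper"]] + 1e-12)
      expect_true(v[["estimate"]] >= 0 && v[["estimate"]] <= 1)
    }
    if (rep$sensitivity[["estimate"]] + rep$specificity[["estimate"]] > 1)
      expect_gte(rep$lr_pos[["estimate"]], rep$lr_neg[["estimate"]])
  }
})
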