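# Discrimination, calibration, decision-analytic and feature-effect
# statistics.

test_that("confusion metrics and DOR match cell arithmetic", {
  probs <- c(rep(0.9, 9), 0.1, 0.9, rep(0.1, 9))
  labels <- c(rep("growth", 10), rep("nongrowth", 10))
  cm <- confusion_metrics(probs, labels, 0.5)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$dor, 81)
  expect_false(cm$dor_corrected)
  expect_equal(cm$sensitivity, 1 - cm$fnr)
  expect_equal(cm$specificity, 1 - cm$fpr)
  expect_equal(cm$dor * (cm$fn * cm$fp), cm$tp * cm$tn)
  # all correct -> zero cells -> Haldane correction flagged
  cm2 <- confusion_metrics(c(0.9, 0.9, 0.1), c("growth", "growth",
                                               "nongrowth"), 0.5)
  expect_true(cm2$dor_corrected)
  # cutoff 0: everything positive
  cm3 <- confusion_metrics(probs, labels, 0)
  expect_equal(cm3$sensitivity, 1)
  expect_equal(cm3$specificity, 0)
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1),
                       c("nongrowth", "nongrowth", "growth", "growth")), 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c("growth", "nongrowth"), 3)), 0.5)
  # 4-point set: concordant 3 of 4 pairs
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("nongrowth", "nongrowth", "growth", "growth")), 0.75)
  pair_auc <- function(p, y) {
    pos <- p[y == "growth"]; neg <- p[y != "growth"]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  withr::with_seed(10, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      y <- sample(c("growth", "nongrowth"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
      if (length(unique(y)) < 2) next
      p <- round(runif(n), 2)  # force ties
      expect_equal(roc_auc(p, y), pair_auc(p, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC and AUCPR agree with pROC on a random set", {
  skip_if_not_installed("pROC")
  withr::with_seed(4, {
    y <- sample(c("growth", "nongrowth"), 40, replace = TRUE)
    p <- runif(40)
  })
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y == "growth", p, levels = c(FALSE, TRUE),
                        direction = "<", quiet = TRUE))
  ))
  expect_equal(roc_auc(p, y), ref, tolerance = 1e-12)
  expect_gte(pr_auc(p, y), 0)
  expect_lte(pr_auc(p, y), 1)
  expect_equal(pr_auc(c(0, 0, 1, 1),
                      c("nongrowth", "nongrowth", "growth", "growth")), 1)
})

test_that("calibration identities hold for constant predictors", {
  y <- c(rep("growth", 64), rep("nongrowth", 36))
  cal <- calibration_metrics(rep(0.64, 100), y)
  expect_equal(cal$citl, 0, tolerance = 1e-12)
  expect_equal(cal$brier, 0.64 * 0.36, tolerance = 1e-12)
  expect_equal(round(cal$brier, 2), 0.23)
  # arbitrary prevalence
  for (prev in c(0.2, 0.5, 0.9)) {
    n <- 200
    y2 <- c(rep("growth", round(prev * n)),
            rep("nongrowth", round((1 - prev) * n)))
    cal2 <- calibration_metrics(rep(prev, n), y2)
    expect_equal(cal2$brier, prev * (1 - prev), tolerance = 1e-12)
  }
  # perfect predictions
  cal3 <- calibration_metrics(c(1, 1, 0), c("growth", "growth", "nongrowth"))
  expect_equal(cal3$brier, 0)
  expect_equal(sum(cal3$curve$n, na.rm = TRUE), 3)
})

test_that("net benefit matches algebra for perfect and toy classifiers", {
  y <- c(rep("growth", 4), rep("nongrowth", 6))
  perfect <- c(rep(0.99, 4), rep(0.01, 6))
  nb <- net_benefit(perfect, y, thresholds = c(0.1, 0.4, 0.9))
  expect_equal(nb$net_benefit, rep(0.4, 3), tolerance = 1e-12)
  # treat-all at t = prevalence is zero
  nb2 <- net_benefit(perfect, y, thresholds = 0.4)
  expect_equal(nb2$treat_all, 0, tolerance = 1e-12)
  # 10-patient toy: 3 TP, 1 FP at t = 0.3
  probs <- c(0.8, 0.7, 0.6, 0.2, 0.5, rep(0.1, 5))
  yy <- c(rep("growth", 4), rep("nongrowth", 6))
  nb3 <- net_benefit(probs, yy, thresholds = 0.3)
  expect_equal(nb3$net_benefit, 0.3 - 0.1 * (3 / 7), tolerance = 1e-12)
  expect_error(net_benefit(probs, yy, thresholds = 1), "inside")
})

test_that("operating points respect their constraints", {
  y <- c("nongrowth", "nongrowth", "growth", "growth")
  p <- c(0.1, 0.2, 0.8, 0.9)
  for (mode in c("rule_in", "rule_out")) {
    op <- operating_point(p, y, mode, 0.95)
    expect_true(op$feasible)
    expect_equal(op$sensitivity, 1)
    expect_equal(op$specificity, 1)
  }
  # overlapping classes, sensitivity 1 required: cutoff at/below min positive
  p2 <- c(0.3, 0.6, 0.5, 0.9)
  op2 <- operating_point(p2, y, "rule_out", 1.0)
  expect_true(op2$feasible)
  expect_lte(op2$cutoff, 0.5)
  expect_equal(op2$sensitivity, 1)
  # infeasible rule-in: specificity 1 unreachable with sens > 0 ... use
  # a constraint above anything achievable
  p3 <- c(0.9, 0.9, 0.1, 0.1)  # anti-predictive
  op3 <- operating_point(p3, y, "rule_in", 0.99)
  expect_false(op3$feasible && op3$sensitivity > 0)
})

test_that("paired bootstrap behaves at the degenerate extremes", {
  y <- rep(c("growth", "nongrowth"), 10)
  pa <- ifelse(y == "growth", 0.9, 0.1)
  # identical models: zero difference, p capped at 1
  same <- paired_bootstrap_auc(pa, pa, y, n_boot = 200, seed = 1)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  # perfect vs anti-perfect: every replicate has dAUC = 1
  anti <- 1 - pa
  comp <- paired_bootstrap_auc(pa, anti, y, n_boot = 200, seed = 1)
  expect_equal(comp$mean_diff, 1)
  expect_equal(comp$p_value, 1 / 200)
  expect_gt(comp$ci_lo, 0)
  # determinism
  c2 <- paired_bootstrap_auc(pa, anti, y, n_boot = 200, seed = 1)
  expect_identical(comp, c2)
})

test_that("permutation importance isolates the predictive component", {
  withr::with_seed(6, {
    x <- cbind(signal = c(rnorm(25, -1.5), rnorm(25, 1.5)),
               noise = rnorm(50))
    y <- rep(c("nongrowth", "growth"), each = 25)
    m <- train_svm(x, y, kernel = "linear", C = 1)
    imp <- permutation_importance(m, x, y, n_perm = 20, seed = 3)
  })
  base_auc <- roc_auc(m$predict_prob(x), y)
  expect_gt(imp$importance[1], 0.8 * (base_auc - 0.5))
  expect_lt(abs(imp$importance[2]), 0.1)
  expect_equal(imp$sign[1], 1)
  imp2 <- permutation_importance(m, x, y, n_perm = 20, seed = 3)
  expect_identical(imp, imp2)
})

test_that("stable feature sets are exact intersections ordered by mean F", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "b", "e"),
               c("b", "c"), c("c", "b", "f"))
  fstats <- lapply(1:5, function(i) c(a = 1, b = 2, c = 5, d = 1, e = 1,
                                      f = 1))
  out <- stable_feature_set(sets, fstats)
  expect_equal(out$name, c("c", "b"))
  expect_identical(stable_feature_set(list(c("a"), c("b")))$name, character(0))
  same <- stable_feature_set(list(c("x", "y"), c("x", "y")))
  expect_setequal(same$name, c("x", "y"))
})

test_that("Cohen's d matches hand arithmetic and flags degenerate input", {
  y <- c(rep("growth", 3), rep("nongrowth", 3))
  expect_equal(cohens_d(c(1, 2, 3, 3, 4, 5), y)$d, -2)
  expect_equal(cohens_d(c(1, 2, 3, 1, 2, 3), y)$d, 0)
  deg <- cohens_d(c(0, 0, 1, 1), c("growth", "growth", "nongrowth",
                                   "nongrowth"))
  expect_true(deg$flagged)
  expect_true(is.na(deg$d))
})

test_that("feature grouping maps completely and picks argmax |d| representatives", {
  groups <- default_feature_groups()
  expect_equal(nrow(groups), 101)
  expect_true(all(groups$group != ""))
  withr::with_seed(13, {
    tab <- tibble::tibble(
      id = sprintf("p%02d", 1:20),
      t2_fo_mean = c(rnorm(10, 0), rnorm(10, 3)),
      t2_fo_median = c(rnorm(10, 0), rnorm(10, 1)),
      ktrans_fo_mean = rnorm(20)
    )
  })
  labs <- rep(c("nongrowth", "growth"), each = 10)
  out <- group_features(c("t2_fo_mean", "t2_fo_median", "ktrans_fo_mean"),
                        tab, labs)
  t2val <- out[out$channel == "t2" & out$group == "value", ]
  expect_equal(t2val$name, "t2_fo_mean")  # larger |d| than the median
  expect_equal(t2val$group_size, 2)
  expect_error(group_features("t2_fo_notafeature", tab, labs), "Unmapped")
})

test_that("the permutation-null AUC band contains 0.5 and is seeded", {
  withr::with_seed(2, {
    p <- runif(60)
    y <- sample(c("growth", "nongrowth"), 60, replace = TRUE,
                prob = c(0.6, 0.4))
  })
  b1 <- auc_permutation_band(p, y, n_perm = 300, seed = 5)
  b2 <- auc_permutation_band(p, y, n_perm = 300, seed = 5)
  expect_identical(b1, b2)
  expect_lt(b1$lower, 0.5)
  expect_gt(b1$upper, 0.5)
})

test_that("evaluate_cv assembles a coherent report", {
  co <- small_cohort()
  grid <- pipeline_grid(kernel = "linear", C = 1, k = 10, n = 2)
  fit <- run_nested_cv(co, "full", grid = grid, seed = 3,
                       outer_folds = 3, inner_folds = 2)
  ev <- evaluate_cv(fit)
  expect_equal(nrow(ev$per_fold), 3)
  expect_true(all(ev$per_fold$auc >= 0 & ev$per_fold$auc <= 1))
  expect_equal(ev$pooled$confusion$sensitivity,
               1 - ev$pooled$confusion$fnr)
  expect_true(nrow(ev$decision_curve) > 0)
  expect_equal(nrow(ev$operating_points), 2)
  # plots build without error
  expect_s3_class(plot_roc(fit), "ggplot")
  expect_s3_class(plot_calibration(fit), "ggplot")
  expect_s3_class(plot_decision_curve(fit), "ggplot")
})
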