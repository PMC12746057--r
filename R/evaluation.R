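# Discrimination, calibration, decision-curve, operating-point,
# model-comparison and feature-importance analytics over out-of-fold
# predictions. Positive class is "growth"; "prob >= cutoff" predicts growth.

label01 <- function(labels) as.integer(as.character(labels) == positive_class)

#' Confusion-matrix metrics at a cutoff
#'
#' Accuracy, sensitivity, specificity, FPR, FNR and the diagnostic odds ratio
#' `DOR = (TP*TN)/(FP*FN)`; when any cell is zero, the Haldane 0.5 continuity
#' correction is applied to the DOR and flagged.
#'
#' @param probs Predicted probabilities.
#' @param labels Labels (positive class `"growth"`).
#' @param cutoff Probability cutoff.
#' @return One-row tibble: tp, fp, tn, fn, accuracy, sensitivity,
#'   specificity, fpr, fnr, dor, dor_corrected.
#' @export
confusion_metrics <- function(probs, labels, cutoff) {
  y <- label01(labels)
  if (!any(y == 1) || !any(y == 0)) abort("Both classes must be present.")
  pred <- as.integer(probs >= cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  corrected <- any(c(tp, fp, tn, fn) == 0)
  cells <- c(tp, fp, tn, fn) + if (corrected) 0.5 else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    fpr = fp / (fp + tn),
    fnr = fn / (fn + tp),
    dor = (cells[1] * cells[3]) / (cells[2] * cells[4]),
    dor_corrected = corrected
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; ties count 1/2.
#'
#' @inheritParams confusion_metrics
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  y <- label01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: `sum over thresholds of (recall_i - recall_{i-1}) *
#' precision_i`, thresholds descending over the distinct predicted
#' probabilities (tied probabilities are grouped).
#'
#' @inheritParams confusion_metrics
#' @return AUCPR in \[0, 1\].
#' @export
pr_auc <- function(probs, labels) {
  y <- label01(labels)
  n1 <- sum(y)
  if (n1 == 0 || n1 == length(y)) return(NA_real_)
  th <- sort(unique(probs), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    sel <- probs >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / n1
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

#' Calibration metrics and binned calibration curve
#'
#' Calibration-in-the-large is the observed event rate minus the mean
#' predicted probability; the Brier score is the mean squared difference
#' between probability and outcome; the curve bins predictions into 10
#' equal-width bins.
#'
#' @inheritParams confusion_metrics
#' @param bins Number of equal-width bins for the curve.
#' @return List: `citl`, `brier`, `curve` (tibble: bin midpoint, mean
#'   predicted, observed rate, n).
#' @export
calibration_metrics <- function(probs, labels, bins = 10) {
  y <- label01(labels)
  probs <- as.numeric(probs)
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1),
              bins)
  curve <- tibble::tibble(bin = seq_len(bins),
                          midpoint = (edges[-1] + edges[-(bins + 1)]) / 2) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, prob = probs, y = y) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(mean_predicted = mean(.data$prob),
                         observed_rate = mean(.data$y),
                         n = dplyr::n(), .groups = "drop"),
      by = "bin"
    )
  list(citl = mean(y) - mean(probs),
       brier = mean((probs - y)^2),
       curve = curve)
}

#' Decision-curve net benefit
#'
#' `NB(t) = TP/N - (FP/N) * t/(1-t)` at each threshold probability `t`, with
#' the treat-all reference `pi - (1-pi) t/(1-t)` and treat-none (0).
#'
#' @inheritParams confusion_metrics
#' @param thresholds Threshold probabilities in (0, 1).
#' @return Tibble: threshold, net_benefit, treat_all, treat_none.
#' @export
net_benefit <- function(probs, labels, thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    abort("`thresholds` must be strictly inside (0, 1).")
  }
  y <- label01(labels)
  n <- length(y)
  prev <- mean(y)
  purrr::map_dfr(thresholds, function(t) {
    pred <- probs >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    tibble::tibble(
      threshold = t,
      net_benefit = tp / n - (fp / n) * t / (1 - t),
      treat_all = prev - (1 - prev) * t / (1 - t),
      treat_none = 0
    )
  })
}

#' Rule-in / rule-out operating points
#'
#' Over the observed probability thresholds, `rule_out` maximizes specificity
#' subject to sensitivity >= `constraint` (high-sensitivity exclusion of
#' growth), `rule_in` maximizes sensitivity subject to specificity >=
#' `constraint`.
#'
#' @inheritParams confusion_metrics
#' @param mode `"rule_in"` or `"rule_out"`.
#' @param constraint Minimum sensitivity (rule_out) or specificity (rule_in).
#' @return One-row tibble: mode, feasible, cutoff, sensitivity, specificity.
#' @export
operating_point <- function(probs, labels, mode, constraint = 0.95) {
  mode <- match.arg(mode, c("rule_in", "rule_out"))
  check_number(constraint, "constraint", lower = 0, upper = 1)
  y <- label01(labels)
  cand <- sort(unique(c(probs, min(probs) - 1e-9)))
  stats <- purrr::map_dfr(cand, function(ct) {
    pred <- probs >= ct
    tibble::tibble(cutoff = ct,
                   sensitivity = sum(pred & y == 1) / sum(y == 1),
                   specificity = sum(!pred & y == 0) / sum(y == 0))
  })
  ok <- if (mode == "rule_out") {
    stats[stats$sensitivity >= constraint, , drop = FALSE]
  } else {
    stats[stats$specificity >= constraint, , drop = FALSE]
  }
  if (!nrow(ok)) {
    return(tibble::tibble(mode = mode, feasible = FALSE, cutoff = NA_real_,
                          sensitivity = NA_real_, specificity = NA_real_))
  }
  best <- if (mode == "rule_out") {
    ok[order(-ok$specificity, ok$cutoff), ][1, ]
  } else {
    ok[order(-ok$sensitivity, ok$cutoff), ][1, ]
  }
  tibble::tibble(mode = mode, feasible = TRUE, cutoff = best$cutoff,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity)
}

#' Paired bootstrap comparison of two models' AUCs
#'
#' Resamples patients with replacement `n_boot` times; each replicate
#' computes `AUC_A - AUC_B` on the same resampled patients. Reports the mean
#' difference, percentile 95% CI, and the two-sided p-value
#' `2 min(frac <= 0, frac >= 0)` floored at `1/n_boot` and capped at 1.
#' Single-class resamples are redrawn (and counted).
#'
#' @param probs_a,probs_b Out-of-fold probabilities of the two models for the
#'   same patients.
#' @param labels Shared labels.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return One-row tibble: mean_diff, ci_lo, ci_hi, p_value, n_redrawn.
#' @export
paired_bootstrap_auc <- function(probs_a, probs_b, labels, n_boot = 1000,
                                 seed = 2024) {
  if (length(probs_a) != length(probs_b) ||
      length(probs_a) != length(labels)) {
    abort("Both models must cover the same patients.")
  }
  y <- as.character(labels)
  n <- length(y)
  with_seed(seed, {
    diffs <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      diffs[b] <- roc_auc(probs_a[idx], y[idx]) - roc_auc(probs_b[idx], y[idx])
    }
    ci <- unname(quantile(diffs, c(0.025, 0.975)))
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    tibble::tibble(mean_diff = mean(diffs), ci_lo = ci[1], ci_hi = ci[2],
                   p_value = min(max(p, 1 / n_boot), 1),
                   n_redrawn = n_redrawn)
  })
}

#' Permutation-null band for the AUC
#'
#' Null distribution of the AUC under label permutation against fixed
#' predicted probabilities; used to judge whether an observed AUC is
#' distinguishable from chance.
#'
#' @inheritParams confusion_metrics
#' @param n_perm Number of label permutations.
#' @param level Central probability mass of the band.
#' @param seed RNG seed.
#' @return List: `lower`, `upper` (central band), `aucs` (null draws).
#' @export
auc_permutation_band <- function(probs, labels, n_perm = 1000, level = 0.95,
                                 seed = 2024) {
  y <- as.character(labels)
  with_seed(seed, {
    aucs <- vapply(seq_len(n_perm), function(b) {
      roc_auc(probs, y[sample.int(length(y))])
    }, numeric(1))
    qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    list(lower = qs[1], upper = qs[2], aucs = aucs)
  })
}

#' Permutation importance of model inputs
#'
#' Mean AUC drop over `n_perm` permutations of one input column, signed by
#' the rank correlation between that column and the predicted probability
#' (negative importance marks association with nongrowth).
#'
#' @param model A `vs_model` from [train_svm()] (anything with a
#'   `predict_prob` function).
#' @param x Input matrix (e.g. PCA component scores).
#' @param labels Labels.
#' @param n_perm Permutations per column.
#' @param seed RNG seed.
#' @return Tibble: component, importance, sign, signed_importance.
#' @export
permutation_importance <- function(model, x, labels, n_perm = 20,
                                   seed = 2024) {
  x <- as.matrix(x)
  base_prob <- model$predict_prob(x)
  base_auc <- roc_auc(base_prob, labels)
  with_seed(seed, {
    purrr::map_dfr(seq_len(ncol(x)), function(jc) {
      drops <- vapply(seq_len(n_perm), function(b) {
        xp <- x
        xp[, jc] <- xp[sample.int(nrow(x)), jc]
        base_auc - roc_auc(model$predict_prob(xp), labels)
      }, numeric(1))
      s <- suppressWarnings(cor(x[, jc], base_prob, method = "spearman"))
      s <- if (is.na(s) || s == 0) 1 else sign(s)
      imp <- mean(drops)
      tibble::tibble(component = jc, importance = imp, sign = s,
                     signed_importance = s * abs(imp))
    })
  })
}

#' Features selected in every cross-validation fold
#'
#' Exact intersection of the per-fold top-k feature name sets, ordered by the
#' mean F statistic across folds.
#'
#' @param fold_sets List of character vectors (per-fold selected names).
#' @param fold_f Optional list of named F-statistic vectors for ordering.
#' @return Tibble: name, mean_f (NA when `fold_f` is absent).
#' @export
stable_feature_set <- function(fold_sets, fold_f = NULL) {
  common <- Reduce(intersect, fold_sets)
  mean_f <- rep(NA_real_, length(common))
  if (!is.null(fold_f) && length(common)) {
    mean_f <- vapply(common, function(nm) {
      mean(vapply(fold_f, function(fs) unname(fs[nm]), numeric(1)))
    }, numeric(1))
  }
  out <- tibble::tibble(name = common, mean_f = mean_f)
  out[order(-replace(out$mean_f, is.na(out$mean_f), -Inf)), ]
}

#' Cohen's d effect size between growing and nongrowing groups
#'
#' `(mean_growth - mean_nongrowth) / pooled SD` with the pooled (sample)
#' standard deviation. Zero pooled SD gives `NA` with `flagged = TRUE`.
#'
#' @param values Numeric vector.
#' @param labels Labels (positive class `"growth"`).
#' @return One-row tibble: d, mean_growth, sd_growth, mean_nongrowth,
#'   sd_nongrowth, flagged.
#' @export
cohens_d <- function(values, labels) {
  y <- label01(labels)
  x1 <- values[y == 1]; x0 <- values[y == 0]
  if (length(x1) < 2 || length(x0) < 2) abort("Need >= 2 values per class.")
  sp2 <- ((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
    (length(x1) + length(x0) - 2)
  flagged <- sp2 == 0
  tibble::tibble(
    d = if (flagged) NA_real_ else (mean(x1) - mean(x0)) / sqrt(sp2),
    mean_growth = mean(x1), sd_growth = sd(x1),
    mean_nongrowth = mean(x0), sd_nongrowth = sd(x0),
    flagged = flagged
  )
}

#' Default representation grouping of the radiomic features
#'
#' Maps every feature of the manifest to a representation group (value,
#' variance, prominence of low/high gray values, heterogeneity, clustering,
#' texture complexity, size/shape), following the standard feature
#' taxonomy. Used by [group_features()]; any other complete mapping can be
#' supplied instead.
#'
#' @return Tibble: `feature` (family_feature), `group`.
#' @export
default_feature_groups <- function() {
  fam_feat <- feature_manifest(channels = "t2")
  key <- paste(fam_feat$family, fam_feat$feature, sep = "_")
  grp <- character(length(key))
  value_feats <- paste0("fo_", c("mean", "median", "rms", "energy",
                                 "total_energy", "minimum", "maximum"))
  var_feats <- paste0("fo_", c("variance", "mad", "robust_mad", "iqr",
                               "range"))
  low_feats <- c("fo_p10", "glrlm_lglre", "glrlm_srlgle", "glrlm_lrlgle",
                 "glszm_lglze", "glszm_salgle", "glszm_lalgle", "gldm_lgle",
                 "gldm_sdlgle", "gldm_ldlgle")
  high_feats <- c("fo_p90", "glcm_autocorrelation", "glcm_joint_average",
                  "glcm_sum_average", "glrlm_hglre", "glrlm_srhgle",
                  "glrlm_lrhgle", "glszm_hglze", "glszm_sahgle",
                  "glszm_lahgle", "gldm_hgle", "gldm_sdhgle", "gldm_ldhgle")
  cluster_feats <- c("glcm_cluster_prominence", "glcm_cluster_shade",
                     "glcm_cluster_tendency", "glcm_sum_squares",
                     "glcm_sum_entropy")
  complexity_feats <- c("glcm_correlation", "glcm_imc1", "glcm_imc2",
                        "glcm_mcc", "glcm_joint_entropy", "fo_entropy",
                        "ngtdm_complexity", "ngtdm_strength",
                        "gldm_dependence_entropy", "glszm_zone_entropy",
                        "glrlm_run_entropy")
  shape_feats <- paste0("shape_", shape_feature_names())
  grp[key %in% value_feats] <- "value"
  grp[key %in% var_feats] <- "variance"
  grp[key %in% low_feats] <- "prominence_low_gray"
  grp[key %in% high_feats] <- "prominence_high_gray"
  grp[key %in% cluster_feats] <- "clustering"
  grp[key %in% complexity_feats] <- "texture_complexity"
  grp[key %in% shape_feats] <- "size_shape"
  grp[grp == ""] <- "heterogeneity"
  tibble::tibble(feature = key, group = grp)
}

#' Group selected features and pick group representatives
#'
#' Groups features by representation, reports per-group class-conditional
#' means/SDs and picks the most discriminative member of each group by
#' maximum absolute Cohen's d.
#'
#' @param feature_names Character vector of (channel-prefixed) feature names.
#' @param feature_table Tibble: `id` + feature columns covering
#'   `feature_names`.
#' @param labels Label per row of `feature_table`.
#' @param grouping Tibble `feature` -> `group`; default
#'   [default_feature_groups()]. Every selected feature must be mapped.
#' @return Tibble, one row per (channel, group): representative feature, its
#'   Cohen's d and class-conditional mean (SD), and group size.
#' @export
group_features <- function(feature_names, feature_table, labels,
                           grouping = default_feature_groups()) {
  strip <- sub("^(t2|ktrans|ve|vp)_", "", feature_names)
  channel <- sub("_.*$", "", feature_names)
  g <- grouping$group[match(strip, grouping$feature)]
  if (any(is.na(g))) {
    abort(paste0("Unmapped feature(s): ",
                 paste(feature_names[is.na(g)], collapse = ", ")))
  }
  effects <- purrr::map_dfr(seq_along(feature_names), function(i) {
    d <- cohens_d(feature_table[[feature_names[i]]], labels)
    dplyr::bind_cols(tibble::tibble(name = feature_names[i],
                                    channel = channel[i], group = g[i]), d)
  })
  dplyr::group_by(effects, .data$channel, .data$group) |>
    dplyr::group_modify(function(df, key) {
      rep_row <- df[which.max(abs(df$d)), ]
      rep_row$group_size <- nrow(df)
      rep_row
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(abs(.data$d)))
}

#' Evaluate a fitted nested-CV model
#'
#' Builds the full evaluation report from a `vs_cv_fit`: per-fold and
#' mean +/- SD discrimination metrics at the per-fold Youden cutoffs, pooled
#' out-of-fold confusion/DOR/calibration, ROC/PR curves (pooled), calibration
#' and decision curves, rule-in/rule-out operating points, and the stable
#' (all-folds) feature set.
#'
#' @param fit A `vs_cv_fit` from [run_nested_cv()].
#' @param rule_out_sens,rule_in_spec Operating-point constraints.
#' @return A `vs_eval` list.
#' @export
evaluate_cv <- function(fit, rule_out_sens = 0.95, rule_in_spec = 0.95) {
  if (!inherits(fit, "vs_cv_fit")) abort("`fit` must be a `vs_cv_fit`.")
  oof <- fit$oof
  per_fold <- purrr::map_dfr(fit$folds, function(fr) {
    rows <- oof[oof$fold == fr$fold, ]
    cm <- confusion_metrics(rows$prob, rows$label, fr$cutoff)
    tibble::tibble(
      fold = fr$fold,
      auc = roc_auc(rows$prob, rows$label),
      aucpr = pr_auc(rows$prob, rows$label),
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity, cutoff = fr$cutoff,
      retained_variance = fr$retained_variance
    )
  })
  pooled_cm <- confusion_metrics(oof$prob, oof$label,
                                 cutoff = mean(per_fold$cutoff))
  calib <- calibration_metrics(oof$prob, oof$label)
  nb <- net_benefit(oof$prob, oof$label)
  ops <- dplyr::bind_rows(
    operating_point(oof$prob, oof$label, "rule_out", rule_out_sens),
    operating_point(oof$prob, oof$label, "rule_in", rule_in_spec)
  )
  stable <- stable_feature_set(
    purrr::map(fit$folds, "selected_features"),
    purrr::map(fit$folds, "f_stats")
  )
  structure(list(
    per_fold = per_fold,
    mean_sd = dplyr::summarise(per_fold, dplyr::across(
      c("auc", "aucpr", "accuracy", "sensitivity", "specificity", "cutoff",
        "retained_variance"),
      list(mean = mean, sd = sd)
    )),
    pooled = list(confusion = pooled_cm, auc = roc_auc(oof$prob, oof$label),
                  aucpr = pr_auc(oof$prob, oof$label),
                  citl = calib$citl, brier = calib$brier),
    calibration_curve = calib$curve,
    decision_curve = nb,
    operating_points = ops,
    stable_features = stable,
    subset = fit$subset
  ), class = "vs_eval")
}

#' @export
print.vs_eval <- function(x, ...) {
  ms <- x$mean_sd
  cat(sprintf("<vs_eval> subset=%s\n", x$subset))
  cat(sprintf("  AUC %.3f +/- %.3f, AUCPR %.3f +/- %.3f\n",
              ms$auc_mean, ms$auc_sd, ms$aucpr_mean, ms$aucpr_sd))
  cat(sprintf("  accuracy %.1f%%, sens %.1f%%, spec %.1f%% at cutoff %.3f +/- %.3f\n",
              100 * ms$accuracy_mean, 100 * ms$sensitivity_mean,
              100 * ms$specificity_mean, ms$cutoff_mean, ms$cutoff_sd))
  cat(sprintf("  pooled: DOR %.1f, calibration-in-the-large %+.3f, Brier %.3f\n",
              x$pooled$confusion$dor, x$pooled$citl, x$pooled$brier))
  cat(sprintf("  stable feature set: %d features\n", nrow(x$stable_features)))
  invisible(x)
}
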