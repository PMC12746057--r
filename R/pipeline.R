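# Nested stratified cross-validated classifier: per-fold fixed-bin-width
# feature extraction -> Z-score standardization -> ANOVA-F top-k selection ->
# PCA to n components -> class-weighted SVM with Platt-style sigmoid
# probabilities fitted on inner-CV out-of-fold decision values -> per-fold
# Youden cutoff applied only to the corresponding validation fold. Every
# fitted statistic derives from training patients only.

positive_class <- "growth"

#' Stratified fold assignment
#'
#' Deterministic stratified partition: within each class, patients are
#' shuffled (seeded) and dealt round-robin, so a 70/40 cohort split 5 ways
#' gives exactly 14 growing and 8 nongrowing patients per fold.
#'
#' @param labels Character/factor vector of class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per patient (1..k).
#' @export
make_folds <- function(labels, k = 5, seed = 2024) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("Class '%s' has fewer members (%d) than folds (%d).",
                  names(tab)[which.min(tab)], min(tab), k))
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score standardization fitted on training rows
#'
#' Centers and scales every feature to training mean 0 and unit (population)
#' variance; the same training statistics are applied to the validation
#' table. Zero-variance or non-finite training features are dropped and
#' logged.
#'
#' @param train,apply_to Numeric data frames / matrices with identical
#'   columns.
#' @return List: `train`, `apply` (matrices), `center`, `scale`, `dropped`
#'   (column names).
#' @export
standardize <- function(train, apply_to = NULL) {
  tr <- as.matrix(train)
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, pop_sd)
  bad <- !is.finite(ctr) | !is.finite(scl) | scl == 0
  dropped <- colnames(tr)[bad]
  tr <- tr[, !bad, drop = FALSE]
  ctr <- ctr[!bad]; scl <- scl[!bad]
  ztr <- sweep(sweep(tr, 2, ctr), 2, scl, `/`)
  zap <- NULL
  if (!is.null(apply_to)) {
    ap <- as.matrix(apply_to)[, colnames(tr), drop = FALSE]
    zap <- sweep(sweep(ap, 2, ctr), 2, scl, `/`)
  }
  list(train = ztr, apply = zap, center = ctr, scale = scl, dropped = dropped)
}

#' ANOVA F statistics and top-k feature selection
#'
#' One-way (two-group) ANOVA F statistic per feature; the k features with the
#' largest statistics are selected, ties broken by column order.
#'
#' @param x Numeric matrix (patients x features).
#' @param labels Two-class label vector.
#' @param k Number of features to keep.
#' @return List: `indices` (length k), `f_stat` (all features, named).
#' @export
select_top_k <- function(x, labels, k) {
  x <- as.matrix(x)
  if (k > ncol(x)) abort("`k` exceeds the number of features.")
  y <- as.character(labels)
  cls <- unique(y)
  if (length(cls) != 2L) abort("Need exactly two classes.")
  n <- nrow(x)
  i1 <- y == cls[1]
  n1 <- sum(i1); n0 <- n - n1
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[!i1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((x[i1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!i1, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)), ifelse(ssb > 0, Inf, 0))
  names(f) <- colnames(x)
  list(indices = order(-f)[seq_len(k)], f_stat = f)
}

#' PCA dimensionality reduction fitted on training rows
#'
#' Principal components from the training covariance; validation rows are
#' projected with the training basis. Retained variance is the fraction of
#' total training variance captured by the first `n` components.
#'
#' @param train Numeric matrix.
#' @param n Number of components (must not exceed the matrix rank).
#' @param apply_to Optional matrix to project with the training basis.
#' @return List: `train` (scores), `apply`, `basis`, `center`, `retained`.
#' @export
pca_reduce <- function(train, n, apply_to = NULL) {
  train <- as.matrix(train)
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n > rank) abort(sprintf("`n` = %d exceeds the training rank (%d).", n, rank))
  basis <- pc$rotation[, seq_len(n), drop = FALSE]
  out_apply <- NULL
  if (!is.null(apply_to)) {
    out_apply <- sweep(as.matrix(apply_to), 2, pc$center) %*% basis
  }
  list(train = pc$x[, seq_len(n), drop = FALSE], apply = out_apply,
       basis = basis, center = pc$center, retained = sum(ev[seq_len(n)]) / sum(ev))
}

balanced_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

#' Train a class-weighted SVM with sigmoid probability mapping
#'
#' Fits an SVM (linear or gaussian/RBF kernel) with balanced class weights
#' `N / (2 N_class)` and a Platt-style sigmoid probability mapping fitted by
#' logistic regression on supplied decision values (typically inner-CV
#' out-of-fold values; falls back to refit values).
#'
#' @param x Numeric matrix of inputs (e.g. PCA components).
#' @param labels Two-class labels; `"growth"` is the positive class.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param C Regularization parameter (> 0).
#' @param gamma_scale Multiplier on the `1/ncol(x)` bandwidth heuristic
#'   (gaussian kernel only).
#' @param class_weighting Use balanced class weights (default `TRUE`).
#' @param calib_dv,calib_labels Decision values and labels for the sigmoid
#'   fit; default: decision values of `x` under the fitted model.
#' @return A `vs_model` list: `svm`, `platt` (function dv -> prob),
#'   `predict_prob(newx)`.
#' @export
train_svm <- function(x, labels, kernel = "gaussian", C = 1, gamma_scale = 1,
                      class_weighting = TRUE, calib_dv = NULL,
                      calib_labels = NULL) {
  check_number(C, "C", lower = 0, allow_equal_lower = FALSE)
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = sort(unique(as.character(labels))))
  if (nlevels(y) != 2L) abort("Need exactly two classes to train the SVM.")
  wts <- if (class_weighting) balanced_weights(y) else NULL
  fit <- e1071::svm(
    x = x, y = y,
    kernel = if (kernel == "gaussian") "radial" else "linear",
    cost = C,
    gamma = if (kernel == "gaussian") gamma_scale / ncol(x) else 1 / ncol(x),
    class.weights = wts, scale = FALSE, probability = FALSE
  )
  dv_of <- function(newx) {
    p <- predict(fit, as.matrix(newx), decision.values = TRUE)
    as.numeric(attr(p, "decision.values"))
  }
  if (is.null(calib_dv)) {
    calib_dv <- dv_of(x)
    calib_labels <- y
  }
  y01 <- as.integer(as.character(calib_labels) == positive_class)
  platt <- fit_platt(calib_dv, y01)
  structure(list(svm = fit, platt = platt, dv = dv_of,
                 predict_prob = function(newx) platt(dv_of(newx))),
            class = "vs_model")
}

# Logistic sigmoid dv -> P(growth); robust to separation (probabilities are
# clipped away from 0/1).
fit_platt <- function(dv, y01) {
  df <- data.frame(y = y01, dv = dv)
  g <- suppressWarnings(glm(y ~ dv, family = binomial(), data = df))
  a <- coef(g)
  function(d) {
    eta <- a[1] + a[2] * d
    p <- 1 / (1 + exp(-eta))
    pmin(pmax(p, 1e-8), 1 - 1e-8)
  }
}

#' Youden-optimal probability cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1` over the observed predicted
#' probabilities under the convention `prob >= cutoff` predicts growth; ties
#' are broken toward the lowest cutoff.
#'
#' @param probs Predicted probabilities.
#' @param labels Labels with positive class `"growth"`.
#' @return The cutoff probability.
#' @export
youden_cutoff <- function(probs, labels) {
  y <- as.character(labels) == positive_class
  if (!any(y) || all(y)) abort("Both classes must be present.")
  cand <- sort(unique(probs))
  j <- vapply(cand, function(ct) {
    pred <- probs >= ct
    sens <- mean(pred[y]); spec <- mean(!pred[!y])
    sens + spec - 1
  }, numeric(1))
  cand[which(j == max(j))[1]]
}

#' Hyper-parameter grid for the nested CV
#'
#' Each element is one candidate configuration. Defaults center on the
#' operating point selected for the full model (gaussian kernel, N_bins = 32,
#' k = 100, n = 25) with a small C grid; wider searches can be built by
#' expanding the argument vectors.
#'
#' @param kernel,C,gamma_scale,n_bins,k,n Vectors of candidate values; the
#'   grid is their cross product, filtered to `n < k`.
#' @return List of config lists.
#' @export
pipeline_grid <- function(kernel = "gaussian", C = c(1, 10), gamma_scale = 1,
                          n_bins = 32, k = 100, n = 25) {
  g <- expand.grid(kernel = kernel, C = C, gamma_scale = gamma_scale,
                   n_bins = n_bins, k = k, n = n,
                   stringsAsFactors = FALSE)
  g <- g[g$n < g$k | is.na(g$k), , drop = FALSE]
  if (!nrow(g)) abort("Empty hyper-parameter grid (need n < k).")
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

baseline_grid <- function(subset) {
  switch(subset,
    volume_only = pipeline_grid(kernel = "linear", C = c(1, 10),
                                n_bins = 32, k = 2, n = 1),
    t2_only = pipeline_grid(kernel = "linear", C = c(1, 10), k = 30, n = 5),
    fos_dce_only = pipeline_grid(kernel = "gaussian", C = c(1, 10),
                                 k = 20, n = 2),
    full = pipeline_grid()
  )
}

subset_columns <- function(feature_names, subset) {
  switch(subset,
    full = grep("^(t2|ktrans|ve|vp)_", feature_names, value = TRUE),
    t2_only = grep("^t2_", feature_names, value = TRUE),
    fos_dce_only = grep("^(ktrans|ve|vp)_fo_", feature_names, value = TRUE),
    volume_only = character(0),
    abort(sprintf("Unknown feature subset '%s'.", subset))
  )
}

# Internal: fit preprocessing + SVM on training rows, return predictions on
# validation rows plus the fitted pieces. For the volume-only subset the
# F-test/PCA stages are bypassed.
fit_stage <- function(xtr, ytr, xval, cfg, volume_only = FALSE) {
  std <- standardize(xtr, xval)
  if (volume_only) {
    model_in_tr <- std$train
    model_in_val <- std$apply
    sel <- list(indices = seq_len(ncol(std$train)),
                f_stat = setNames(rep(NA_real_, ncol(std$train)),
                                  colnames(std$train)))
    pca <- list(retained = 1)
  } else {
    k_eff <- min(cfg$k, ncol(std$train))
    sel <- select_top_k(std$train, ytr, k_eff)
    xsel_tr <- std$train[, sel$indices, drop = FALSE]
    xsel_val <- std$apply[, sel$indices, drop = FALSE]
    n_eff <- min(cfg$n, nrow(xsel_tr) - 1L, ncol(xsel_tr))
    pca <- pca_reduce(xsel_tr, n_eff, xsel_val)
    model_in_tr <- pca$train
    model_in_val <- pca$apply
  }
  svm_fit <- e1071::svm(
    x = model_in_tr,
    y = factor(as.character(ytr), levels = c("growth", "nongrowth")),
    kernel = if (cfg$kernel == "gaussian") "radial" else "linear",
    cost = cfg$C,
    gamma = (cfg$gamma_scale %||% 1) / ncol(model_in_tr),
    class.weights = balanced_weights(ytr), scale = FALSE
  )
  dv_tr <- as.numeric(attr(predict(svm_fit, model_in_tr,
                                   decision.values = TRUE),
                           "decision.values"))
  dv_val <- as.numeric(attr(predict(svm_fit, model_in_val,
                                    decision.values = TRUE),
                            "decision.values"))
  list(dv_tr = dv_tr, dv_val = dv_val, sel = sel, pca = pca,
       dropped = std$dropped, svm = svm_fit, std = std,
       train_in = model_in_tr)
}

#' Run the nested stratified cross-validated growth model
#'
#' The full pipeline on a cohort: per outer fold, modality-dependent bin
#' widths are fitted on the training patients, features extracted, and the
#' candidate configurations of `grid` scored by inner stratified CV; the
#' winning configuration is refitted on the outer training set. Probabilities
#' come from a sigmoid fitted on inner-CV out-of-fold decision values, and
#' the Youden cutoff of each training fold is applied only to its validation
#' fold. With `subset` the same pipeline runs on a restricted feature set
#' (ablation baselines); `volume_only` bypasses selection and PCA.
#'
#' @param cohort A `vs_cohort` from [generate_cohort()].
#' @param subset `"full"`, `"volume_only"`, `"t2_only"` or `"fos_dce_only"`.
#' @param grid List of candidate configurations ([pipeline_grid()]); default
#'   depends on `subset`.
#' @param outer_folds,inner_folds Fold counts (both stratified).
#' @param seed RNG seed controlling fold assignment.
#' @param labels Optional label vector overriding the cohort manifest (used
#'   e.g. for permutation nulls).
#' @param source Optional precomputed [precompute_features()] object.
#' @param fold_cache Optional fold-feature cache returned by a previous run
#'   with identical labels and seed (reused across feature subsets).
#' @param leak If `TRUE`, deliberately fit bin widths and all per-fold
#'   statistics on training AND validation patients. This exists only so the
#'   test suite can demonstrate that the default path is leakage-free; never
#'   use it for results.
#' @return A `vs_cv_fit` object; see [glance.vs_cv_fit()] / [tidy.vs_cv_fit()].
#' @export
run_nested_cv <- function(cohort, subset = "full", grid = NULL,
                          outer_folds = 5, inner_folds = 5, seed = 2024,
                          labels = NULL, source = NULL, fold_cache = NULL,
                          leak = FALSE) {
  if (!inherits(cohort, "vs_cohort")) abort("`cohort` must be a `vs_cohort`.")
  subset <- match.arg(subset, c("full", "volume_only", "t2_only",
                                "fos_dce_only"))
  grid <- grid %||% baseline_grid(subset)
  if (!length(grid)) abort("Empty hyper-parameter grid.")
  man <- cohort$manifest
  labels <- labels %||% man$binarized
  usable <- !is.na(labels)
  n_undet <- sum(!usable)
  if (n_undet > 0) {
    inform(sprintf("%d patients with undetermined labels excluded.", n_undet))
  }
  ids <- man$id[usable]
  labels <- as.character(labels[usable])
  volumes <- man$baseline_volume[usable]
  volume_only <- subset == "volume_only"
  if (!volume_only && is.null(source)) source <- precompute_features(cohort)
  fold <- make_folds(labels, outer_folds, seed)
  cache_key <- paste0(paste(labels, collapse = ""), "|", seed, "|",
                      outer_folds, "|", leak)
  if (!is.null(fold_cache) && !identical(fold_cache$key, cache_key)) {
    abort("`fold_cache` was built under different labels/seed; refusing to reuse.")
  }
  cache <- fold_cache %||% list(key = cache_key, tabs = list())
  fold_results <- vector("list", outer_folds)
  oof <- vector("list", outer_folds)
  all_dropped <- character(0)
  for (f in seq_len(outer_folds)) {
    tr_idx <- which(fold != f)
    va_idx <- which(fold == f)
    stat_idx <- if (leak) seq_along(ids) else tr_idx
    # candidate feature tables per n_bins (training-fitted widths)
    get_features <- function(n_bins) {
      if (volume_only) {
        return(tibble::tibble(id = ids, volume = volumes))
      }
      key <- paste(f, n_bins, sep = ":")
      if (!is.null(cache$tabs[[key]])) return(cache$tabs[[key]])
      pat <- source$patients[match(ids, source$ids)]
      ranges <- purrr::map_dfr(pat[stat_idx], function(p) {
        tibble::tibble(channel = names(p$ranges), range = unname(p$ranges))
      })
      widths <- widths_from_ranges(ranges, n_bins)
      tab <- extract_cohort_features(
        structure(list(patients = pat, ids = ids),
                  class = "vs_feature_source"),
        widths
      )
      cache$tabs[[key]] <<- tab
      tab
    }
    feat_cols <- NULL
    config_scores <- rep(NA_real_, length(grid))
    inner_seed <- child_seed(seed, f)
    inner_fold <- make_folds(labels[tr_idx], inner_folds, inner_seed)
    for (ci in seq_along(grid)) {
      cfg <- grid[[ci]]
      tab <- get_features(cfg$n_bins)
      cols <- if (volume_only) "volume" else subset_columns(names(tab), subset)
      X <- as.matrix(tab[, cols, drop = FALSE])
      aucs <- numeric(inner_folds)
      for (g in seq_len(inner_folds)) {
        itr <- tr_idx[inner_fold != g]
        iva <- tr_idx[inner_fold == g]
        st <- fit_stage(X[itr, , drop = FALSE], labels[itr],
                        X[iva, , drop = FALSE], cfg, volume_only)
        platt <- fit_platt(st$dv_tr,
                           as.integer(labels[itr] == positive_class))
        aucs[g] <- roc_auc(platt(st$dv_val), labels[iva])
      }
      config_scores[ci] <- mean(aucs)
    }
    best <- which.max(config_scores)
    cfg <- grid[[best]]
    tab <- get_features(cfg$n_bins)
    cols <- if (volume_only) "volume" else subset_columns(names(tab), subset)
    X <- as.matrix(tab[, cols, drop = FALSE])
    # inner-CV out-of-fold decision values on the training set for the
    # sigmoid and the Youden cutoff
    oof_dv <- rep(NA_real_, length(tr_idx))
    for (g in seq_len(inner_folds)) {
      itr <- tr_idx[inner_fold != g]
      iva <- tr_idx[inner_fold == g]
      st <- fit_stage(X[itr, , drop = FALSE], labels[itr],
                      X[iva, , drop = FALSE], cfg, volume_only)
      oof_dv[inner_fold == g] <- st$dv_val
    }
    platt <- fit_platt(oof_dv, as.integer(labels[tr_idx] == positive_class))
    train_probs <- platt(oof_dv)
    cutoff <- youden_cutoff(train_probs, labels[tr_idx])
    final <- fit_stage(X[stat_idx, , drop = FALSE],
                       labels[stat_idx], X[va_idx, , drop = FALSE],
                       cfg, volume_only)
    val_probs <- platt(final$dv_val)
    all_dropped <- union(all_dropped, final$dropped)
    sel_names <- names(final$sel$f_stat)[final$sel$indices]
    sel_f <- final$sel$f_stat[final$sel$indices]
    fold_results[[f]] <- list(
      fold = f, config = cfg, inner_auc = config_scores[best],
      train_ids = ids[tr_idx], validation_ids = ids[va_idx],
      stat_fit_ids = ids[stat_idx],
      selected_features = sel_names, f_stats = sel_f,
      retained_variance = final$pca$retained,
      cutoff = cutoff, dropped_features = final$dropped
    )
    oof[[f]] <- tibble::tibble(
      id = ids[va_idx], fold = f, label = labels[va_idx],
      prob = val_probs, cutoff = cutoff
    )
  }
  structure(list(
    folds = fold_results,
    oof = dplyr::bind_rows(oof),
    subset = subset, grid = grid, seed = seed,
    outer_folds = outer_folds, inner_folds = inner_folds,
    n_excluded_undetermined = n_undet,
    dropped_features = all_dropped,
    leak = leak,
    fold_cache = cache
  ), class = "vs_cv_fit")
}

#' Run an ablation baseline model
#'
#' The identical nested-CV pipeline restricted to a feature subset: the
#' baseline tumor volume alone (selection and PCA bypassed), the 101
#' T2-based features, or the 54 first-order statistics of the DCE-derived
#' parameter maps.
#'
#' @inheritParams run_nested_cv
#' @export
run_baseline <- function(cohort, subset, ...) {
  if (identical(subset, "full")) {
    abort("`subset` must be one of volume_only, t2_only, fos_dce_only.")
  }
  run_nested_cv(cohort, subset = subset, ...)
}

#' @export
print.vs_cv_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<vs_cv_fit> subset=%s, %d outer folds, seed %d\n",
              x$subset, x$outer_folds, x$seed))
  cat(sprintf("  AUC %.3f +/- %.3f | accuracy %.1f%% | cutoff %.3f +/- %.3f\n",
              g$auc_mean, g$auc_sd, 100 * g$accuracy_mean,
              g$cutoff_mean, g$cutoff_sd))
  invisible(x)
}
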