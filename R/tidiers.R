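# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-fold results of a nested-CV fit
#'
#' One row per outer fold: validation AUC/AUCPR, accuracy/sensitivity/
#' specificity at the fold's Youden cutoff, the cutoff, retained PCA
#' variance, and the selected configuration.
#'
#' @param x A `vs_cv_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @export
tidy.vs_cv_fit <- function(x, ...) {
  ev <- evaluate_cv(x)
  cfgs <- purrr::map_dfr(x$folds, function(fr) {
    tibble::tibble(kernel = fr$config$kernel, C = fr$config$C,
                   n_bins = fr$config$n_bins, k = fr$config$k,
                   n = fr$config$n,
                   n_selected = length(fr$selected_features))
  })
  dplyr::bind_cols(ev$per_fold, cfgs)
}

#' One-row summary of a nested-CV fit
#'
#' Mean +/- SD of the fold-level metrics plus pooled out-of-fold AUC, DOR,
#' calibration-in-the-large and Brier score.
#'
#' @param x A `vs_cv_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.vs_cv_fit <- function(x, ...) {
  ev <- evaluate_cv(x)
  dplyr::bind_cols(
    tibble::tibble(subset = x$subset, n_patients = nrow(x$oof),
                   outer_folds = x$outer_folds, seed = x$seed),
    ev$mean_sd,
    tibble::tibble(pooled_auc = ev$pooled$auc, pooled_aucpr = ev$pooled$aucpr,
                   pooled_dor = ev$pooled$confusion$dor,
                   citl = ev$pooled$citl, brier = ev$pooled$brier,
                   n_stable_features = nrow(ev$stable_features))
  )
}

#' Per-fold metric rows of an evaluation report
#'
#' @param x A `vs_eval`.
#' @param ... Unused.
#' @return Tibble of fold-level metrics.
#' @export
tidy.vs_eval <- function(x, ...) x$per_fold

#' One-row summary of an evaluation report
#'
#' @param x A `vs_eval`.
#' @param ... Unused.
#' @return One-row tibble of mean +/- SD and pooled metrics.
#' @export
glance.vs_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(subset = x$subset),
    x$mean_sd,
    tibble::tibble(pooled_auc = x$pooled$auc,
                   pooled_dor = x$pooled$confusion$dor,
                   citl = x$pooled$citl, brier = x$pooled$brier)
  )
}
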