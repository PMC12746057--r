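# ggplot2 graphics for evaluation reports.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline labs
#'   geom_step theme_minimal geom_hline coord_cartesian autoplot geom_col
NULL

roc_points <- function(probs, labels) {
  y <- label01(labels)
  th <- c(Inf, sort(unique(probs), decreasing = TRUE))
  purrr::map_dfr(th, function(t) {
    pred <- probs >= t
    tibble::tibble(fpr = sum(pred & y == 0) / sum(y == 0),
                   tpr = sum(pred & y == 1) / sum(y == 1))
  })
}

#' ROC curve of pooled out-of-fold predictions
#'
#' @param fit A `vs_cv_fit`.
#' @return A ggplot object.
#' @export
plot_roc <- function(fit) {
  pts <- roc_points(fit$oof$prob, fit$oof$label)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "False positive rate", y = "Sensitivity",
         title = sprintf("ROC (pooled out-of-fold), AUC = %.3f",
                         roc_auc(fit$oof$prob, fit$oof$label))) +
    theme_minimal()
}

#' Calibration curve of pooled out-of-fold predictions
#'
#' @param fit A `vs_cv_fit`.
#' @param bins Number of equal-width probability bins.
#' @return A ggplot object.
#' @export
plot_calibration <- function(fit, bins = 10) {
  calib <- calibration_metrics(fit$oof$prob, fit$oof$label, bins = bins)
  cc <- calib$curve[!is.na(calib$curve$mean_predicted), ]
  ggplot(cc, aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    geom_point(aes(size = .data$n)) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Mean predicted probability", y = "Observed growth rate",
         title = sprintf("Calibration: in-the-large %+.3f, Brier %.3f",
                         calib$citl, calib$brier), size = "patients") +
    theme_minimal()
}

#' Decision curve (net benefit) of pooled out-of-fold predictions
#'
#' @param fit A `vs_cv_fit`.
#' @param thresholds Threshold probabilities.
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(fit, thresholds = seq(0.05, 0.95, 0.05)) {
  nb <- net_benefit(fit$oof$prob, fit$oof$label, thresholds)
  long <- tidyr::pivot_longer(nb, c("net_benefit", "treat_all", "treat_none"),
                              names_to = "strategy", values_to = "nb")
  ggplot(long, aes(x = .data$threshold, y = .data$nb,
                   colour = .data$strategy)) +
    geom_line() +
    coord_cartesian(ylim = c(-0.1, NA)) +
    labs(x = "Threshold probability", y = "Net benefit",
         colour = NULL, title = "Decision curve") +
    theme_minimal()
}

#' @export
autoplot.vs_cv_fit <- function(object, type = c("roc", "calibration",
                                                "decision"), ...) {
  type <- match.arg(type)
  switch(type,
         roc = plot_roc(object),
         calibration = plot_calibration(object),
         decision = plot_decision_curve(object))
}

#' Permutation-importance bar chart
#'
#' @param importance Tibble from [permutation_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot(importance,
         aes(x = factor(.data$component), y = .data$signed_importance)) +
    geom_col() +
    geom_hline(yintercept = 0, colour = "grey40") +
    labs(x = "Principal component", y = "Signed permutation importance",
         title = "Component importance (negative = nongrowth association)") +
    theme_minimal()
}
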