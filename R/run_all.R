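# End-to-end orchestration: simulate -> label -> extract -> train (full +
# three ablation baselines) -> evaluate -> compare, with stage timings and
# per-stage attrition counts.

#' Run the full growth-prediction study end to end
#'
#' Generates (or accepts) a cohort, runs the nested-CV full model and the
#' three ablation baselines, evaluates each, and compares the full model's
#' AUC against every baseline with a paired bootstrap.
#'
#' @param config A [cohort_config()] (ignored when `cohort` is given).
#' @param cohort Optional pre-generated `vs_cohort`.
#' @param grid Optional hyper-parameter grid for the full model.
#' @param baselines Baseline subsets to run.
#' @param n_boot Bootstrap replicates for the model comparisons.
#' @param seed Seed for folds and bootstrap.
#' @return A `vs_run` list: `cohort`, `fits`, `evals`, `comparisons`,
#'   `manifest` (stage log tibble).
#' @export
run_vs_study <- function(config = cohort_config(), cohort = NULL, grid = NULL,
                         baselines = c("volume_only", "t2_only",
                                       "fos_dce_only"),
                         n_boot = 1000, seed = 2024) {
  if (!is.null(grid)) {
    for (cfg in grid) {
      if (!is.na(cfg$k) && cfg$n >= cfg$k) {
        abort(sprintf("Config with n = %d >= k = %d rejected.", cfg$n, cfg$k))
      }
    }
  }
  stages <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    stages[[stage]] <<- tibble::tibble(stage = stage,
                                       seconds = proc.time()[["elapsed"]] - t0)
    out
  }
  cohort <- cohort %||% tick("simulate", generate_cohort(config))
  source <- tick("precompute", precompute_features(cohort))
  fits <- list()
  fits$full <- tick("train_full",
                    run_nested_cv(cohort, "full", grid = grid, seed = seed,
                                  source = source))
  cache <- fits$full$fold_cache
  for (bs in baselines) {
    fits[[bs]] <- tick(paste0("train_", bs),
                       run_nested_cv(cohort, bs, seed = seed, source = source,
                                     fold_cache = if (bs == "volume_only")
                                       NULL else cache))
  }
  evals <- tick("evaluate", purrr::map(fits, evaluate_cv))
  comparisons <- tick("compare", {
    purrr::map_dfr(baselines, function(bs) {
      stopifnot(identical(fits$full$oof$id[order(fits$full$oof$id)],
                          fits[[bs]]$oof$id[order(fits[[bs]]$oof$id)]))
      a <- fits$full$oof[order(fits$full$oof$id), ]
      b <- fits[[bs]]$oof[order(fits[[bs]]$oof$id), ]
      dplyr::bind_cols(
        tibble::tibble(model_a = "full", model_b = bs),
        paired_bootstrap_auc(a$prob, b$prob, a$label, n_boot = n_boot,
                             seed = seed)
      )
    })
  })
  structure(list(
    cohort = cohort, fits = fits, evals = evals, comparisons = comparisons,
    manifest = dplyr::bind_rows(stages),
    seed = seed
  ), class = "vs_run")
}

#' @export
print.vs_run <- function(x, ...) {
  cat("<vs_run>\n")
  for (nm in names(x$fits)) {
    g <- glance(x$fits[[nm]])
    cat(sprintf("  %-14s AUC %.3f +/- %.3f | accuracy %.1f%% | Brier %.3f\n",
                nm, g$auc_mean, g$auc_sd, 100 * g$accuracy_mean, g$brier))
  }
  cat("  paired bootstrap (full vs baseline):\n")
  for (i in seq_len(nrow(x$comparisons))) {
    cc <- x$comparisons[i, ]
    cat(sprintf("    vs %-13s dAUC %+0.3f (CI95 %+0.3f..%+0.3f, p = %.3g)\n",
                cc$model_b, cc$mean_diff, cc$ci_lo, cc$ci_hi, cc$p_value))
  }
  invisible(x)
}
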