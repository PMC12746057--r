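# Growth labeling: patient-specific, volume-dependent thresholds of
# significant relative volumetric change, and the consecutive-scan
# growing / stable / shrinking rule.

#' Volume-dependent significant-change threshold model
#'
#' A tumor's measurable relative volume change depends on its size: small
#' tumors need a larger relative change before it exceeds measurement
#' variability. The default model is a clamped power law
#' `theta(V) = clamp(a * V^-b, floor, ceiling)` whose coefficients are chosen
#' so that `theta(0.2 cm^3) = 0.30` and `theta(2.3 cm^3) = 0.05`, spanning the
#' approximately 5%-30% range reported for vestibular schwannoma volumetry.
#' Any non-increasing function of volume can be injected via `fun`.
#'
#' @param a,b Power-law coefficients (used when `fun` is `NULL`).
#' @param floor,ceiling Lower/upper clamp for the threshold fraction.
#' @param fun Optional function `volume_cm3 -> threshold fraction`; it is
#'   still clamped to `[floor, ceiling]`.
#' @return A `vs_threshold_model` object.
#' @export
threshold_model <- function(a = NULL, b = NULL, floor = 0.05, ceiling = 0.30,
                            fun = NULL) {
  check_number(floor, "floor", lower = 0, upper = 1)
  check_number(ceiling, "ceiling", lower = floor, upper = 1)
  if (is.null(fun)) {
    if (is.null(b)) b <- log(ceiling / floor) / log(2.3 / 0.2)
    if (is.null(a)) a <- ceiling * 0.2^b
    check_number(a, "a", lower = 0, allow_equal_lower = FALSE)
    check_number(b, "b", lower = 0)
    fun <- function(v) a * v^(-b)
  }
  structure(list(fun = fun, a = a, b = b, floor = floor, ceiling = ceiling),
            class = "vs_threshold_model")
}

#' Patient-specific growth threshold
#'
#' Evaluates the volume-dependent threshold of significant relative volume
#' change for a baseline tumor volume.
#'
#' @param baseline_volume Tumor volume at diagnosis, cm^3 (vectorized).
#' @param model A [threshold_model()].
#' @return Threshold fraction(s) in `[model$floor, model$ceiling]`.
#' @export
loam_threshold <- function(baseline_volume, model = threshold_model()) {
  if (!inherits(model, "vs_threshold_model")) {
    abort("`model` must be built with `threshold_model()`.")
  }
  if (any(!is.finite(baseline_volume)) || any(baseline_volume <= 0)) {
    abort("`baseline_volume` must be positive.")
  }
  pmin(pmax(model$fun(baseline_volume), model$floor), model$ceiling)
}

#' Label a tumor's volumetric course
#'
#' Applies the consecutive-scan rule: relative volume change of every
#' follow-up scan is computed against the volume at diagnosis; a tumor is
#' *growing* (*shrinking*) if the change exceeds `+threshold` (falls below
#' `-threshold`) on at least two consecutive follow-up scans, and *stable*
#' otherwise. If both patterns occur, growth takes precedence and the case is
#' flagged. Fewer than two follow-ups give the label `undetermined` (excluded
#' from model training, distinct from stable).
#'
#' @param baseline_volume Volume at diagnosis, cm^3.
#' @param followups Data frame or tibble with columns `months` and
#'   `volume_cm3`, or a list of `c(months, volume)` pairs.
#' @param model A [threshold_model()].
#' @return A tibble with columns `label` (growing/stable/shrinking/
#'   undetermined), `binarized` (growth/nongrowth/NA), `threshold`, and
#'   `conflict` (both growth and shrinkage patterns present).
#' @export
classify_course <- function(baseline_volume, followups,
                            model = threshold_model()) {
  check_number(baseline_volume, "baseline_volume", lower = 0,
               allow_equal_lower = FALSE)
  if (is.list(followups) && !is.data.frame(followups)) {
    followups <- do.call(rbind, lapply(followups, function(x) {
      data.frame(months = x[[1]], volume_cm3 = x[[2]])
    }))
  }
  if (!all(c("months", "volume_cm3") %in% names(followups))) {
    abort("`followups` needs columns `months` and `volume_cm3`.")
  }
  followups <- followups[order(followups$months), , drop = FALSE]
  if (anyDuplicated(followups$months)) {
    abort("Follow-up times must be strictly increasing.")
  }
  theta <- loam_threshold(baseline_volume, model)
  n <- nrow(followups)
  if (n < 2L) {
    return(tibble::tibble(label = "undetermined", binarized = NA_character_,
                          threshold = theta, conflict = FALSE))
  }
  rel <- followups$volume_cm3 / baseline_volume - 1
  two_consecutive <- function(hit) any(hit[-1] & hit[-length(hit)])
  grew <- two_consecutive(rel > theta)
  shrank <- two_consecutive(rel < -theta)
  label <- if (grew) "growing" else if (shrank) "shrinking" else "stable"
  if (grew && shrank) {
    warn("Both growth and shrinkage patterns present; labeling as growing.")
  }
  tibble::tibble(
    label = label,
    binarized = if (label == "growing") "growth" else "nongrowth",
    threshold = theta,
    conflict = grew && shrank
  )
}

#' Label a cohort's volume trajectories
#'
#' Applies [classify_course()] to a long table of follow-up volumes.
#'
#' @param volumes Tibble with columns `id`, `months`, `volume_cm3`; the
#'   baseline is supplied separately per patient in `baselines` (columns `id`,
#'   `baseline_volume`).
#' @param baselines Tibble mapping `id` to `baseline_volume` (cm^3).
#' @param model A [threshold_model()].
#' @return Tibble with one row per patient: `id`, `label`, `binarized`,
#'   `threshold`, `conflict`.
#' @export
label_cohort <- function(volumes, baselines, model = threshold_model()) {
  if (!all(c("id", "months", "volume_cm3") %in% names(volumes))) {
    abort("`volumes` needs columns `id`, `months`, `volume_cm3`.")
  }
  dplyr::group_by(volumes, .data$id) |>
    dplyr::group_modify(function(df, key) {
      bl <- baselines$baseline_volume[match(key$id, baselines$id)]
      classify_course(bl, df[, c("months", "volume_cm3")], model)
    }) |>
    dplyr::ungroup()
}
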