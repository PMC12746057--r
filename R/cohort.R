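# Seeded synthetic cohort generator. Emulates the statistical structure of a
# wait-and-scan vestibular schwannoma cohort: log-normal baseline volumes,
# ellipsoidal tumor masks with optional interior cysts, class-conditional
# Gaussian-random-field parameter maps (growing tumors: higher Ktrans/vp
# means; nongrowing: higher ve dispersion and longer ve correlation length;
# smoother T2 texture in growing tumors), extended-Tofts-consistent DCE
# signal curves, and follow-up volume trajectories consistent with the
# consecutive-scan labeling rule.

#' Class-conditional map statistics for the generator
#'
#' One row per (channel, class): patient-level mean and between-patient SD of
#' the ROI mean, within-ROI voxel SD, and spatial correlation length (mm) of
#' the Gaussian random field. Defaults place the class contrasts in the
#' directions reported for growing vs nongrowing tumors: growing tumors have
#' higher mean Ktrans and vp, lower ve dispersion and shorter ve correlation
#' length, and smoother (more correlated) T2 texture.
#'
#' @return Tibble with columns `channel`, `class`, `mean`, `between_sd`,
#'   `voxel_sd`, `corr_length`.
#' @export
default_class_effects <- function() {
  tibble::tribble(
    ~channel, ~class,       ~mean,  ~between_sd, ~voxel_sd, ~corr_length,
    "t2",     "growing",    0,      0.25,        1.0,       3.5,
    "t2",     "nongrowing", 0,      0.25,        1.0,       1.8,
    "ktrans", "growing",    0.15,   0.07,        0.05,      2.0,
    "ktrans", "nongrowing", 0.09,   0.05,        0.05,      2.0,
    "ve",     "growing",    0.30,   0.05,        0.10,      2.0,
    "ve",     "nongrowing", 0.30,   0.05,        0.22,      4.5,
    "vp",     "growing",    0.046,  0.025,       0.015,     2.0,
    "vp",     "nongrowing", 0.026,  0.013,       0.015,     2.0
  )
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions: 110 patients, 64% growing, baseline
#' volumes log-normal with median 0.7 cm^3 and sigma fitted to the reported
#' IQR 0.2-2.3 cm^3 (truncated to a clinically plausible 0.05-15 cm^3),
#' 21% cystic tumors, follow-up scans at 12, 24 and 48 months, seed 2024.
#'
#' @param n_patients Cohort size (>= 10).
#' @param growth_prevalence Fraction of growing tumors, in (0, 1).
#' @param volume_log_median Median baseline volume, cm^3.
#' @param volume_log_sigma Log-scale SD of baseline volume.
#' @param volume_range Truncation range for baseline volumes, cm^3.
#' @param grid_spacing Isotropic voxel spacing, mm.
#' @param class_effects Tibble as from [default_class_effects()].
#' @param cyst_probability Probability that a tumor has a cystic component.
#' @param shrink_fraction Fraction of nongrowing tumors that regress (the
#'   remainder are stable); default 15/40.
#' @param followup_months Scan times in months after diagnosis.
#' @param noise_sd DCE signal noise SD (a.u.) when series are generated.
#' @param include_dce Generate the 4D DCE series per patient (off by default:
#'   the prediction pipeline consumes the parameter maps; series generation is
#'   exercised by the kinetics round-trip tools).
#' @param acquisition An [acquisition_params()].
#' @param threshold A [threshold_model()] used both to build and to label the
#'   volume trajectories.
#' @param seed Integer RNG seed.
#' @return A `vs_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 110,
                          growth_prevalence = 0.64,
                          volume_log_median = 0.7,
                          volume_log_sigma = 1.81,
                          volume_range = c(0.05, 15),
                          grid_spacing = 1.5,
                          class_effects = default_class_effects(),
                          cyst_probability = 0.21,
                          shrink_fraction = 15 / 40,
                          followup_months = c(12, 24, 48),
                          noise_sd = 5,
                          include_dce = FALSE,
                          acquisition = acquisition_params(),
                          threshold = threshold_model(),
                          seed = 2024) {
  check_number(n_patients, "n_patients", lower = 10)
  check_number(growth_prevalence, "growth_prevalence", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  check_number(volume_log_median, "volume_log_median", lower = 0,
               allow_equal_lower = FALSE)
  check_number(volume_log_sigma, "volume_log_sigma", lower = 0)
  check_number(grid_spacing, "grid_spacing", lower = 0,
               allow_equal_lower = FALSE)
  check_number(cyst_probability, "cyst_probability", lower = 0, upper = 1)
  check_number(shrink_fraction, "shrink_fraction", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  req <- c("channel", "class", "mean", "between_sd", "voxel_sd", "corr_length")
  if (!all(req %in% names(class_effects))) {
    abort("`class_effects` must have columns channel, class, mean, between_sd, voxel_sd, corr_length.")
  }
  if (any(class_effects$between_sd < 0) || any(class_effects$voxel_sd < 0)) {
    abort("`class_effects` variances (between_sd, voxel_sd) must be >= 0.")
  }
  if (length(followup_months) < 2L || any(diff(followup_months) <= 0)) {
    abort("`followup_months` must be >= 2 strictly increasing times.")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    growth_prevalence = growth_prevalence,
    volume_log_median = volume_log_median,
    volume_log_sigma = volume_log_sigma,
    volume_range = volume_range,
    grid_spacing = grid_spacing,
    class_effects = class_effects,
    cyst_probability = cyst_probability,
    shrink_fraction = shrink_fraction,
    followup_months = followup_months,
    noise_sd = noise_sd,
    include_dce = include_dce,
    acquisition = acquisition,
    threshold = threshold,
    seed = as.integer(seed)
  ), class = "vs_cohort_config")
}

# Gaussian random field on grid `dm`: white noise smoothed at correlation
# length `corr_mm`, standardized to zero mean / unit SD, scaled and shifted.
random_field <- function(dm, mean, sd, corr_mm, spacing) {
  if (sd == 0) return(array(mean, dm))
  w <- array(rnorm(prod(dm)), dm)
  if (corr_mm > 0) {
    w <- gaussian_smooth3d(w, rep(corr_mm, 3) / spacing)
  }
  w <- (w - mean(w)) / sd(w)
  mean + sd * w
}

# Voxelized ellipsoid mask with anisotropy ratios in [0.5, 1]; returns the
# mask and the primary radius (mm).
ellipsoid_mask <- function(volume_cm3, spacing, ratios) {
  vol_mm3 <- volume_cm3 * 1000
  a <- (3 * vol_mm3 / (4 * pi * ratios[1] * ratios[2]))^(1 / 3)
  radii <- c(a, a * ratios[1], a * ratios[2])
  dm <- pmax(as.integer(ceiling(2 * radii / spacing)) + 7L, 9L)
  ctr <- (dm + 1) / 2
  gx <- ((seq_len(dm[1]) - ctr[1]) * spacing / radii[1])^2
  gy <- ((seq_len(dm[2]) - ctr[2]) * spacing / radii[2])^2
  gz <- ((seq_len(dm[3]) - ctr[3]) * spacing / radii[3])^2
  d2 <- outer(outer(gx, gy, `+`), gz, `+`)
  mask <- array(as.numeric(d2 <= 1), dm)
  list(mask = mask, radii = radii, center = ctr)
}

#' Generate class-conditional parameter maps
#'
#' Builds one smoothed Gaussian random field per channel (T2, Ktrans, ve, vp)
#' with the statistics given by `class_effects` for `true_class`, clipped to
#' physical ranges (Ktrans >= 0 min^-1; ve, vp in (0, 1]).
#'
#' @param true_class `"growing"` or `"nongrowing"`.
#' @param roi_mask Binary 3D array (nonempty); fields are generated on its
#'   grid.
#' @param class_effects Tibble as [default_class_effects()].
#' @param spacing Voxel spacing, mm.
#' @return Named list of 3D arrays: `t2`, `ktrans`, `ve`, `vp`.
#' @export
generate_parameter_maps <- function(true_class, roi_mask,
                                    class_effects = default_class_effects(),
                                    spacing = 1.5) {
  check_binary_array(roi_mask, "roi_mask")
  if (sum(roi_mask) == 0) abort("`roi_mask` is empty.")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dm <- dim(roi_mask)
  eff <- class_effects[class_effects$class == true_class, , drop = FALSE]
  if (!nrow(eff)) abort(sprintf("No class effects for class '%s'.", true_class))
  out <- list()
  for (ch in vs_channels()) {
    e <- eff[eff$channel == ch, , drop = FALSE]
    if (!nrow(e)) abort(sprintf("No class effects for channel '%s'.", ch))
    mu_pat <- rnorm(1, e$mean, e$between_sd)
    f <- random_field(dm, mu_pat, e$voxel_sd, e$corr_length, spacing)
    f <- switch(ch,
      ktrans = pmin(pmax(f, 0), 2),
      ve = pmin(pmax(f, 1e-4), 1),
      vp = pmin(pmax(f, 1e-4), 1),
      f
    )
    out[[ch]] <- f
  }
  out
}

#' Simulate a DCE signal series from parameter maps
#'
#' Forward-simulates the extended Tofts tissue concentration for every masked
#' voxel, converts to an SPGR signal time course (baseline T10 = 1.4 s,
#' M0 = 1000) and adds Gaussian noise. Unmasked voxels carry the constant
#' baseline signal.
#'
#' @param maps Named list with `ktrans`, `ve`, `vp` arrays.
#' @param mask Binary 3D array.
#' @param acquisition An [acquisition_params()].
#' @param aif A `vs_aif`.
#' @param noise_sd Gaussian signal noise SD, a.u.
#' @param t10 Baseline T1, s.
#' @param m0 Equilibrium magnetization, a.u.
#' @return List with `signal` (4D array), `time_grid` (s), `s_pre` (noiseless
#'   baseline signal).
#' @export
generate_dce_series <- function(maps, mask, acquisition = acquisition_params(),
                                aif = aif_biexponential(), noise_sd = 0,
                                t10 = 1.4, m0 = 1000) {
  tg <- acquisition$time_grid
  if (any(tg < 0) || any(diff(tg) <= 0)) abort("Nonpositive/disordered time grid.")
  check_binary_array(mask, "mask")
  dm <- dim(mask)
  nt <- length(tg)
  s_pre <- spgr_signal(m0, t10, acquisition$dce_flip, acquisition$TR)
  sig <- array(s_pre, c(dm, nt))
  idx <- which(mask > 0)
  nvox <- prod(dm)
  for (v in idx) {
    ct <- etm_forward(maps$ktrans[v], maps$ve[v], maps$vp[v], aif, tg)
    r1t <- 1 / t10 + acquisition$r1 * ct
    s <- spgr_signal(m0, 1 / r1t, acquisition$dce_flip, acquisition$TR)
    sig[v + (seq_len(nt) - 1L) * nvox] <- s
  }
  if (noise_sd > 0) sig <- sig + array(rnorm(length(sig), 0, noise_sd), dim(sig))
  list(signal = sig, time_grid = tg, s_pre = s_pre)
}

#' Generate a follow-up volume trajectory consistent with a target label
#'
#' Growing tumors follow exponential growth whose relative change exceeds the
#' patient-specific threshold on every scan (hence on two consecutive scans);
#' shrinking tumors mirror this downward; stable tumors fluctuate within half
#' the threshold. The trajectory therefore round-trips through
#' [classify_course()] to the intended label.
#'
#' @param true_class `"growing"` or `"nongrowing"`.
#' @param baseline_volume Volume at diagnosis, cm^3.
#' @param threshold A [threshold_model()].
#' @param followup_months Scan times, months.
#' @param shrink_fraction Probability that a nongrowing tumor regresses.
#' @return Tibble with columns `months`, `volume_cm3`, and attribute
#'   `course` (growing/stable/shrinking).
#' @export
generate_followup_volumes <- function(true_class, baseline_volume,
                                      threshold = threshold_model(),
                                      followup_months = c(12, 24, 48),
                                      shrink_fraction = 15 / 40) {
  check_number(baseline_volume, "baseline_volume", lower = 0,
               allow_equal_lower = FALSE)
  theta <- loam_threshold(baseline_volume, threshold)
  m1 <- followup_months[1]
  course <- if (true_class == "growing") {
    "growing"
  } else if (runif(1) < shrink_fraction) "shrinking" else "stable"
  vols <- switch(course,
    growing = {
      u <- runif(1, 1.3, 2.5)
      lam <- log(1 + u * theta) / m1
      baseline_volume * exp(lam * followup_months)
    },
    shrinking = {
      u <- runif(1, 1.3, 2.5)
      lam <- -log(1 - min(u * theta, 0.8)) / m1
      baseline_volume * exp(-lam * followup_months)
    },
    stable = {
      baseline_volume *
        (1 + runif(length(followup_months), -0.5 * theta, 0.5 * theta))
    }
  )
  out <- tibble::tibble(months = followup_months, volume_cm3 = vols)
  attr(out, "course") <- course
  out
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort of patient records under `config`: exactly
#' `round(n_patients * growth_prevalence)` growing tumors, baseline volumes
#' log-normal (independent of class), ellipsoidal masks with optional interior
#' cyst spheres, class-conditional parameter maps, follow-up trajectories that
#' label-round-trip, and (optionally) DCE signal series. Deterministic given
#' the config seed.
#'
#' @param config A [cohort_config()].
#' @return A `vs_cohort` list: `patients` (list of records), `manifest`
#'   (tibble: id, true_class, label, binarized, baseline_volume, n_voxels,
#'   has_cyst), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "vs_cohort_config")) {
    abort("`config` must be built with `cohort_config()`.")
  }
  with_seed(config$seed, {
    n <- config$n_patients
    n_grow <- round(n * config$growth_prevalence)
    classes <- sample(c(rep("growing", n_grow),
                        rep("nongrowing", n - n_grow)))
    sp <- config$grid_spacing
    meanlog <- log(config$volume_log_median)
    plo <- stats::plnorm(config$volume_range[1], meanlog, config$volume_log_sigma)
    phi <- stats::plnorm(config$volume_range[2], meanlog, config$volume_log_sigma)
    target_vols <- stats::qlnorm(runif(n, plo, phi), meanlog,
                                 config$volume_log_sigma)
    patients <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("P%03d", i)
      ratios <- runif(2, 0.5, 1)
      em <- ellipsoid_mask(target_vols[i], sp, ratios)
      mask <- vs_mask(em$mask, spacing = rep(sp, 3))
      voxvol <- sp^3
      baseline_volume <- sum(mask) * voxvol / 1000
      cyst <- array(0, dim(mask))
      has_cyst <- runif(1) < config$cyst_probability
      if (has_cyst) {
        rc <- runif(1, 0.15, 0.35) * min(em$radii)
        off <- runif(3, -0.3, 0.3) * em$radii / sp
        ctr <- em$center + off
        co <- mask_coords(mask)
        d2 <- colSums((t(co) - ctr)^2) * sp^2
        cidx <- which(d2 <= rc^2)
        if (length(cidx)) {
          lin <- co[cidx, , drop = FALSE]
          cyst[lin] <- 1
        }
      }
      channels <- generate_parameter_maps(classes[i], mask,
                                          config$class_effects, spacing = sp)
      followups <- generate_followup_volumes(
        classes[i], baseline_volume, config$threshold,
        config$followup_months, config$shrink_fraction
      )
      dce <- NULL
      if (config$include_dce) {
        dce <- generate_dce_series(channels, unclass(mask),
                                   config$acquisition,
                                   noise_sd = config$noise_sd)
      }
      lab <- classify_course(baseline_volume, followups, config$threshold)
      patients[[i]] <- list(
        id = id, true_class = classes[i], baseline_volume = baseline_volume,
        followups = followups, roi_mask = mask, cyst_mask = cyst,
        channels = channels, dce = dce, acquisition = config$acquisition
      )
      rows[[i]] <- tibble::tibble(
        id = id, true_class = classes[i], label = lab$label,
        binarized = lab$binarized, baseline_volume = baseline_volume,
        n_voxels = sum(mask), has_cyst = has_cyst
      )
    }
    structure(list(patients = patients, manifest = dplyr::bind_rows(rows),
                   config = config),
              class = "vs_cohort")
  })
}

#' @export
print.vs_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<vs_cohort> %d patients (%d growing, %d nongrowing), seed %d\n",
              nrow(m), sum(m$binarized == "growth"),
              sum(m$binarized == "nongrowth"), x$config$seed))
  cat(sprintf("  baseline volume: median %.2f cm^3 (IQR %.2f-%.2f)\n",
              median(m$baseline_volume),
              quantile(m$baseline_volume, 0.25),
              quantile(m$baseline_volume, 0.75)))
  invisible(x)
}
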