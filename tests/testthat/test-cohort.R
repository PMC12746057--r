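# Synthetic cohort generator: prevalence exactness, determinism, label
# round-trip, physical ranges, and class-effect structure.

test_that("growing count equals round(n * prevalence) exactly", {
  co <- generate_cohort(cohort_config(n_patients = 110,
                                      growth_prevalence = 0.64, seed = 2024))
  expect_equal(sum(co$manifest$true_class == "growing"), 70)
  expect_equal(sum(co$manifest$true_class == "nongrowing"), 40)
})

test_that("the generator is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 10, growth_prevalence = 0.5, seed = 2024)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(cohort_config(n_patients = 10,
                                      growth_prevalence = 0.5, seed = 2025))
  expect_false(identical(serialize(a, NULL), serialize(c2, NULL)))
})

test_that("every generated label round-trips through classify_course", {
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(cohort_config(n_patients = 12, seed = seed))
    m <- co$manifest
    expect_equal(m$binarized,
                 ifelse(m$true_class == "growing", "growth", "nongrowth"))
  }
})

test_that("parameter maps respect physical ranges everywhere", {
  co <- small_cohort()
  for (p in co$patients) {
    expect_true(all(p$channels$ktrans >= 0))
    expect_true(all(p$channels$ve > 0 & p$channels$ve <= 1))
    expect_true(all(p$channels$vp > 0 & p$channels$vp <= 1))
  }
})

test_that("masks are nonempty, cysts are subsets, and volumes match masks", {
  co <- small_cohort()
  sp <- co$config$grid_spacing
  for (p in co$patients) {
    expect_gt(sum(p$roi_mask), 0)
    expect_true(all(p$cyst_mask <= p$roi_mask))
    expect_equal(p$baseline_volume, sum(p$roi_mask) * sp^3 / 1000)
    expect_true(all(diff(p$followups$months) > 0))
  }
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_patients = 5), "n_patients")
  expect_error(cohort_config(growth_prevalence = 1.2), "growth_prevalence")
  expect_error(cohort_config(cyst_probability = -0.1), "cyst_probability")
  bad_eff <- default_class_effects()
  bad_eff$voxel_sd[1] <- -1
  expect_error(cohort_config(class_effects = bad_eff), "variance")
})

test_that("zero-variance class effects give spatially constant maps", {
  eff <- default_class_effects()
  eff$voxel_sd <- 0
  eff$between_sd <- 0
  mask <- cube_mask(4)
  withr::with_seed(1, {
    maps <- generate_parameter_maps("growing", mask, eff, spacing = 1.5)
  })
  for (ch in c("ktrans", "ve", "vp")) {
    expect_equal(length(unique(as.numeric(maps[[ch]]))), 1)
  }
  expect_equal(unique(as.numeric(maps$ktrans)),
               eff$mean[eff$channel == "ktrans" & eff$class == "growing"])
})

test_that("growing-class ROI mean ktrans sits near the class setpoint", {
  withr::with_seed(21, {
    mask <- cube_mask(6)
    means <- replicate(30, {
      m <- generate_parameter_maps("growing", mask, spacing = 1.5)
      mean(m$ktrans[mask > 0])
    })
  })
  expect_lt(abs(mean(means) - 0.15), 0.03)
})

test_that("nongrowing ve fields have higher GLCM cluster prominence on average", {
  withr::with_seed(31, {
    mask <- cube_mask(6)
    cp <- function(cls) {
      replicate(20, {
        m <- generate_parameter_maps(cls, mask, spacing = 1.5)
        d <- discretize(m$ve, mask, 0.7 / 32)
        glcm_features(d)[["cluster_prominence"]]
      })
    }
    expect_gt(mean(cp("nongrowing")), mean(cp("growing")))
  })
})

test_that("follow-up trajectories honor course-specific construction", {
  th <- threshold_model()
  withr::with_seed(5, {
    for (i in 1:10) {
      fu <- generate_followup_volumes("growing", 0.7, th)
      expect_equal(classify_course(0.7, fu, th)$label, "growing")
    }
    shr <- 0L
    for (i in 1:40) {
      fu <- generate_followup_volumes("nongrowing", 0.7, th)
      lab <- classify_course(0.7, fu, th)
      expect_equal(lab$binarized, "nongrowth")
      expect_equal(attr(fu, "course"),
                   lab$label)
      shr <- shr + (lab$label == "shrinking")
    }
    expect_gt(shr, 0)  # both nongrowing modes occur
  })
})

test_that("stable trajectories with noise at half the threshold stay stable", {
  th <- threshold_model()
  withr::with_seed(9, {
    for (i in 1:20) {
      fu <- generate_followup_volumes("nongrowing", 1.0, th)
      if (attr(fu, "course") == "stable") {
        rel <- abs(fu$volume_cm3 / 1.0 - 1)
        expect_true(all(rel <= 0.5 * loam_threshold(1.0, th) + 1e-12))
      }
    }
  })
})

test_that("noiseless DCE voxels round-trip through the fitter", {
  mask <- array(0, c(3, 3, 1)); mask[2, 2, 1] <- 1
  maps <- list(ktrans = array(0.15, c(3, 3, 1)),
               ve = array(0.30, c(3, 3, 1)),
               vp = array(0.05, c(3, 3, 1)))
  acq <- acquisition_params()
  ser <- generate_dce_series(maps, mask, acq, noise_sd = 0)
  conc <- concentration_from_signal(
    ser$signal[2, 2, 1, ], 1.4, acq)
  fit <- fit_etm_voxel(conc$concentration, aif_biexponential(), acq$time_grid)
  expect_lt(abs(fit$ktrans / 0.15 - 1), 0.01)
  expect_lt(abs(fit$ve / 0.30 - 1), 0.01)
  expect_lt(abs(fit$vp / 0.05 - 1), 0.01)
  # zero-parameter voxel: signal stays at baseline
  maps0 <- list(ktrans = array(0, c(3, 3, 1)), ve = array(0.3, c(3, 3, 1)),
                vp = array(0, c(3, 3, 1)))
  ser0 <- generate_dce_series(maps0, mask, acq, noise_sd = 0)
  expect_true(all(abs(ser0$signal - ser0$s_pre) < 1e-9))
})

test_that("doubling the DCE noise doubles the fit residual SD", {
  mask <- array(1, c(10, 10, 1))
  maps <- list(ktrans = array(0.15, dim(mask)), ve = array(0.3, dim(mask)),
               vp = array(0.05, dim(mask)))
  acq <- acquisition_params(time_grid = seq(0, 300, by = 12))
  resid_sd <- function(noise, seed) {
    withr::with_seed(seed, {
      ser <- generate_dce_series(maps, mask, acq, noise_sd = noise)
    })
    fit <- fit_etm_map(ser$signal, mask, acq, aif_biexponential(), t10 = 1.4)
    median(fit$rmse[mask > 0], na.rm = TRUE)
  }
  r1 <- resid_sd(2, 123)
  r2 <- resid_sd(4, 123)
  expect_gt(r2 / r1, 1.6)
  expect_lt(r2 / r1, 2.4)
})
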