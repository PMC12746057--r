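# SPGR signal model, VFA T1 mapping, signal <-> concentration, and the
# extended Tofts model in both directions.

test_that("SPGR limits behave and match the Bloch steady-state recursion", {
  expect_equal(spgr_signal(1000, 1, 1e-9, 0.005), 0, tolerance = 1e-6)
  expect_equal(spgr_signal(1000, 1, 30, 50), 1000 * sin(30 * pi / 180),
               tolerance = 1e-6)
  # steady-state recursion oracle: Mz -> (Mz cos a) relaxing over TR
  M0 <- 1000; T1 <- 1.0; TR <- 0.005; a <- 15 * pi / 180
  E1 <- exp(-TR / T1)
  mz <- M0
  for (i in 1:20000) mz <- M0 * (1 - E1) + mz * cos(a) * E1
  expect_equal(spgr_signal(M0, T1, 15, TR), mz * sin(a), tolerance = 1e-6)
  expect_error(spgr_signal(1000, -1, 15, 0.005), "positive")
})

test_that("VFA T1 fit recovers T10 noiselessly and degrades gracefully", {
  angles <- c(2, 15); TR <- 0.005
  s <- spgr_signal(800, 1.2, angles, TR)
  fit <- fit_t1_vfa(s, angles, TR)
  expect_true(fit$ok)
  expect_lt(abs(fit$t10 / 1.2 - 1), 0.001)
  expect_lt(abs(fit$m0 / 800 - 1), 0.001)
  # identical signals at both angles: degenerate
  bad <- fit_t1_vfa(c(100, 100), angles, TR)
  # slope from equal signals is either invalid or out of (0,1)
  expect_false(isTRUE(bad$ok) && is.finite(bad$t10) &&
                 abs(bad$t10 - 1.2) < 0.1)
  # Monte-Carlo at 1% noise: median |T10 error| < 5%
  withr::with_seed(99, {
    errs <- replicate(100, {
      sn <- s * (1 + rnorm(2, 0, 0.01))
      f <- fit_t1_vfa(sn, angles, TR)
      if (f$ok) abs(f$t10 / 1.2 - 1) else NA_real_
    })
    expect_lt(median(errs, na.rm = TRUE), 0.05)
  })
})

test_that("signal-to-concentration inverts the SPGR enhancement exactly", {
  acq <- acquisition_params()
  ct <- etm_forward(0.2, 0.3, 0.05, aif_biexponential(), acq$time_grid)
  r1t <- 1 / 1.4 + acq$r1 * ct
  s <- spgr_signal(1000, 1 / r1t, acq$dce_flip, acq$TR)
  out <- concentration_from_signal(s, 1.4, acq)
  expect_lt(max(abs(out$concentration - ct)), 1e-6)
  expect_equal(out$n_clipped, 0)
  # flat signal -> zero concentration
  flat <- concentration_from_signal(rep(s[1], length(s)), 1.4, acq)
  expect_lt(max(abs(flat$concentration)), 1e-10)
  # doubling r1 halves the recovered concentration
  acq2 <- acquisition_params(r1 = 2 * acq$r1)
  out2 <- concentration_from_signal(s, 1.4, acq2)
  expect_equal(out2$concentration, out$concentration / 2, tolerance = 1e-10)
})

test_that("extended Tofts forward model reduces correctly and matches quadrature", {
  aif <- aif_biexponential()
  t <- seq(0, 300, by = 3)
  # ktrans = 0: pure plasma term
  expect_equal(etm_forward(0, 0.3, 0.07, aif, t), 0.07 * eval_aif(aif, t))
  expect_error(etm_forward(0.1, 0, 0.05, aif, t), "positive")
  # adaptive-quadrature oracle at 5 time points (2 s grid resolves the
  # bolus upslope)
  t <- seq(0, 300, by = 2)
  kt <- 0.15; ve <- 0.30; vp <- 0.05
  kep <- kt / ve
  ct <- etm_forward(kt, ve, vp, aif, t)
  cp_min <- function(tm) eval_aif(aif, tm * 60)  # tm in minutes
  for (ti in c(90, 150, 210, 270, 300)) {
    tm <- ti / 60
    oracle <- vp * cp_min(tm) + kt * stats::integrate(
      function(u) cp_min(u) * exp(-kep * (tm - u)), 0, tm,
      rel.tol = 1e-10, subdivisions = 400)$value
    expect_lt(abs(ct[t == ti] / oracle - 1), 0.001)
  }
})

test_that("early-time tissue concentration increases with ktrans", {
  aif <- aif_biexponential()
  t <- seq(0, 300, by = 6)
  sup <- t > aif$onset
  prev <- etm_forward(0.02, 0.3, 0.02, aif, t)
  for (kt in c(0.05, 0.1, 0.2, 0.5)) {
    cur <- etm_forward(kt, 0.3, 0.02, aif, t)
    expect_true(all(cur[sup] > prev[sup]))
    prev <- cur
  }
})

test_that("voxel fit recovers noiseless parameters within 1%", {
  aif <- aif_biexponential()
  t <- seq(0, 300, by = 6)
  for (p in list(c(0.15, 0.30, 0.05), c(0.05, 0.15, 0.02),
                 c(0.4, 0.5, 0.1))) {
    ct <- etm_forward(p[1], p[2], p[3], aif, t)
    fit <- fit_etm_voxel(ct, aif, t)
    expect_true(fit$converged)
    expect_lt(abs(fit$ktrans / p[1] - 1), 0.01)
    expect_lt(abs(fit$ve / p[2] - 1), 0.01)
    expect_lt(abs(fit$vp / p[3] - 1), 0.01)
  }
})

test_that("an all-zero curve yields ktrans = vp = 0 with ve flagged", {
  fit <- fit_etm_voxel(rep(0, 40), aif_biexponential(), seq(0, 234, by = 6))
  expect_equal(fit$ktrans, 0)
  expect_equal(fit$vp, 0)
  expect_true(is.na(fit$ve))
  expect_equal(fit$flag, "ve_unidentifiable")
})

test_that("NLLS beats a 0.01-resolution bounded grid search on a noisy curve", {
  aif <- aif_biexponential()
  t <- seq(0, 300, by = 6)
  withr::with_seed(3, {
    ct <- etm_forward(0.15, 0.30, 0.05, aif, t) + rnorm(length(t), 0, 0.01)
  })
  lower <- c(0.01, 0.10, 0.00); upper <- c(0.30, 0.50, 0.10)
  fit <- fit_etm_voxel(ct, aif, t, lower = lower, upper = upper)
  grid <- expand.grid(kt = seq(lower[1], upper[1], by = 0.01),
                      ve = seq(lower[2], upper[2], by = 0.01),
                      vp = seq(lower[3], upper[3], by = 0.01))
  rmse <- vapply(seq_len(nrow(grid)), function(i) {
    sqrt(mean((etm_forward(grid$kt[i], grid$ve[i], grid$vp[i], aif, t) -
                 ct)^2))
  }, numeric(1))
  expect_lte(fit$rmse, min(rmse) + 1e-10)
})

test_that("map fitting round-trips a small noiseless synthetic series", {
  # 3 baseline frames keep the whole baseline before the 30 s contrast onset
  acq <- acquisition_params(time_grid = seq(0, 300, by = 10),
                            baseline_frames = 3)
  mask <- array(0, c(3, 3, 1)); mask[1:2, 1:2, 1] <- 1
  withr::with_seed(8, {
    maps <- list(
      ktrans = array(runif(9, 0.05, 0.3), c(3, 3, 1)),
      ve = array(runif(9, 0.2, 0.5), c(3, 3, 1)),
      vp = array(runif(9, 0.01, 0.08), c(3, 3, 1))
    )
  })
  ser <- generate_dce_series(maps, mask, acq, noise_sd = 0)
  fit <- fit_etm_map(ser$signal, mask, acq, aif_biexponential(), t10 = 1.4)
  idx <- which(mask > 0)
  expect_lt(max(abs(fit$ktrans[idx] / maps$ktrans[idx] - 1)), 0.01)
  expect_lt(max(abs(fit$ve[idx] / maps$ve[idx] - 1)), 0.01)
  expect_lt(max(abs(fit$vp[idx] / maps$vp[idx] - 1)), 0.01)
  expect_true(all(is.na(fit$ktrans[-idx])))
  # single-voxel mask: one fitted voxel, rest sentinel
  m1 <- array(0, c(3, 3, 1)); m1[2, 2, 1] <- 1
  f1 <- fit_etm_map(ser$signal, m1, acq, aif_biexponential(), t10 = 1.4)
  expect_equal(sum(!is.na(f1$ktrans)), 1)
  expect_error(fit_etm_map(ser$signal, array(0, c(3, 3, 1)), acq,
                           aif_biexponential()), "empty")
})
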