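# DCE-MRI pharmacokinetics: SPGR signal model, variable-flip-angle T1
# mapping, signal <-> gadolinium concentration conversion, and the extended
# Tofts model (ETM) in both directions (forward simulation and bounded
# voxelwise fitting of Ktrans, ve, vp).
#
# Unit conventions: time grids are in seconds at the interface; rate constants
# (Ktrans, kep, AIF decay rates) are min^-1 and conversion happens once,
# inside each function. Concentrations are mM.

#' DCE acquisition parameters
#'
#' @param TR Repetition time, s.
#' @param flip_angles Flip angles (degrees) of the variable-flip-angle T1
#'   mapping acquisition; at least two distinct angles in (0, 90].
#' @param dce_flip Flip angle (degrees) of the dynamic series.
#' @param r1 Longitudinal relaxivity of the contrast agent, s^-1 mM^-1.
#' @param time_grid Acquisition times of the dynamic frames, s, strictly
#'   increasing, starting at 0.
#' @param baseline_frames Number of pre-contrast frames (>= 1).
#' @return An `vs_acquisition` list.
#' @export
acquisition_params <- function(TR = 0.005,
                               flip_angles = c(2, 15),
                               dce_flip = 15,
                               r1 = 4.5,
                               time_grid = seq(0, 300, by = 6),
                               baseline_frames = 5) {
  check_number(TR, "TR", lower = 0, allow_equal_lower = FALSE)
  if (length(flip_angles) < 2L || any(flip_angles <= 0) || any(flip_angles > 90)) {
    abort("`flip_angles` must be >= 2 angles in (0, 90] degrees.")
  }
  check_number(dce_flip, "dce_flip", lower = 0, upper = 90,
               allow_equal_lower = FALSE)
  check_number(r1, "r1", lower = 0, allow_equal_lower = FALSE)
  if (length(time_grid) < 2L || any(diff(time_grid) <= 0)) {
    abort("`time_grid` must be strictly increasing.")
  }
  if (any(time_grid < 0)) abort("`time_grid` must be nonnegative (seconds).")
  check_number(baseline_frames, "baseline_frames", lower = 1,
               upper = length(time_grid))
  structure(list(TR = TR, flip_angles = flip_angles, dce_flip = dce_flip,
                 r1 = r1, time_grid = as.numeric(time_grid),
                 baseline_frames = as.integer(baseline_frames)),
            class = "vs_acquisition")
}

#' Spoiled gradient-echo steady-state signal
#'
#' `S = M0 sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-TR/T1)`.
#'
#' @param M0 Equilibrium magnetization, arbitrary units.
#' @param T1 Longitudinal relaxation time, s (vectorized).
#' @param alpha Flip angle, degrees.
#' @param TR Repetition time, s.
#' @return Signal in the units of `M0`.
#' @export
spgr_signal <- function(M0, T1, alpha, TR) {
  if (any(!is.finite(T1)) || any(T1 <= 0)) abort("`T1` must be positive.")
  check_number(TR, "TR", lower = 0, allow_equal_lower = FALSE)
  a <- alpha * pi / 180
  E1 <- exp(-TR / T1)
  M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Variable-flip-angle T1 estimation
#'
#' Linearizes the SPGR equation as `S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)`
#' and solves by least squares; the slope gives `E1` and hence `T10`.
#'
#' @param signals Signal per flip angle (same order as `flip_angles`).
#' @param flip_angles Degrees, >= 2 distinct values.
#' @param TR Repetition time, s.
#' @return List with `t10` (s), `m0`, and `ok`; degenerate inputs (collinear
#'   points or slope outside (0, 1)) give `ok = FALSE` with `NA` estimates.
#' @export
fit_t1_vfa <- function(signals, flip_angles, TR) {
  if (length(signals) != length(flip_angles) || length(signals) < 2L) {
    abort("Need one signal per flip angle, with >= 2 angles.")
  }
  a <- flip_angles * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  if (sd(x) == 0) {
    return(list(t10 = NA_real_, m0 = NA_real_, ok = FALSE))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    return(list(t10 = NA_real_, m0 = NA_real_, ok = FALSE))
  }
  list(t10 = -TR / log(slope), m0 = intercept / (1 - slope), ok = TRUE)
}

#' Population arterial input function
#'
#' Biexponential plasma concentration with a smooth bolus-arrival upslope:
#' `Cp(t) = (a1 exp(-m1 tau) + a2 exp(-m2 tau)) (1 - exp(-tau / rise))` for
#' `tau = t - onset >= 0`, and 0 before onset. Defaults follow the classical
#' population model for a standard single dose (amplitudes in mM, decay rates
#' in min^-1); the upslope makes `Cp` continuous at onset, which keeps the
#' grid-native convolution accurate.
#'
#' @param a1,a2 Amplitudes, mM.
#' @param m1,m2 Decay rates, min^-1.
#' @param onset Contrast arrival time, s.
#' @param rise Bolus arrival time constant, min.
#' @return A `vs_aif` object.
#' @export
aif_biexponential <- function(a1 = 3.99 * 0.1, a2 = 4.78 * 0.1,
                              m1 = 0.144, m2 = 0.0111, onset = 30,
                              rise = 0.08) {
  for (nm in c("a1", "a2")) check_number(get(nm), nm, lower = 0)
  for (nm in c("m1", "m2")) check_number(get(nm), nm, lower = 0)
  check_number(onset, "onset", lower = 0)
  check_number(rise, "rise", lower = 0, allow_equal_lower = FALSE)
  structure(list(form = "biexponential", a1 = a1, a2 = a2, m1 = m1, m2 = m2,
                 onset = onset, rise = rise), class = "vs_aif")
}

#' Evaluate an arterial input function
#'
#' @param aif A `vs_aif` object.
#' @param t Times, s.
#' @return Plasma concentration, mM (0 before onset).
#' @export
eval_aif <- function(aif, t) {
  if (!inherits(aif, "vs_aif")) abort("`aif` must be a `vs_aif` object.")
  tau_min <- pmax(t - aif$onset, 0) / 60
  cp <- (aif$a1 * exp(-aif$m1 * tau_min) + aif$a2 * exp(-aif$m2 * tau_min)) *
    (1 - exp(-tau_min / aif$rise))
  cp[t < aif$onset] <- 0
  cp
}

#' Extended Tofts model forward simulation
#'
#' Tissue concentration
#' `Ct(t) = vp Cp(t) + Ktrans Int_0^t Cp(u) exp(-kep (t - u)) du` with
#' `kep = Ktrans / ve`, evaluated by trapezoidal discretization of the
#' convolution on the acquisition time grid.
#'
#' @param ktrans Volume transfer constant, min^-1 (>= 0).
#' @param ve Extravascular extracellular volume fraction, in (0, 1].
#' @param vp Plasma volume fraction, in \[0, 1\].
#' @param aif A `vs_aif`.
#' @param t Time grid, s, strictly increasing.
#' @return Tissue concentration, mM, at each time point.
#' @export
etm_forward <- function(ktrans, ve, vp, aif, t) {
  if (!is.numeric(ve) || ve <= 0) abort("`ve` must be positive.")
  if (ktrans < 0) abort("`ktrans` must be nonnegative.")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  cp <- eval_aif(aif, t)
  if (ktrans == 0) return(vp * cp)
  tm <- t / 60
  kep <- ktrans / ve
  n <- length(tm)
  # E[i, j] = exp(-kep (t_i - t_j)) for j <= i, trapezoid weights on grid
  dt <- diff(tm)
  w <- numeric(n)
  conv <- numeric(n)
  lag <- outer(tm, tm, "-")
  E <- exp(-kep * lag)
  E[lag < 0] <- 0
  integrand <- sweep(E, 2, cp, `*`)
  for (i in 2:n) {
    conv[i] <- trapz(tm[1:i], integrand[i, 1:i])
  }
  vp * cp + ktrans * conv
}

# Cumulative trapezoidal integral of y over x, same length as x.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Linearized ETM initialization: Ct = B1 * int Cp - B2 * int Ct + B3 * Cp
# with B1 = Ktrans + kep vp, B2 = kep, B3 = vp.
etm_linear_init <- function(ct, cp, tm) {
  A <- cbind(cumtrapz(tm, cp), -cumtrapz(tm, ct), cp)
  fit <- tryCatch(qr.solve(A, ct), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) return(NULL)
  kep <- fit[2]; vp <- fit[3]
  ktrans <- fit[1] - kep * vp
  if (!is.finite(ktrans) || kep <= 0 || ktrans <= 0) return(NULL)
  c(ktrans = ktrans, ve = ktrans / kep, vp = vp)
}

#' Fit the extended Tofts model to one concentration-time curve
#'
#' Bounded nonlinear least squares on (Ktrans, ve, vp), initialized from the
#' linearized ETM solution (midpoint of the bounds if that fails). Bounds
#' default to Ktrans in \[0, 2\] min^-1, ve in \[1e-3, 1\], vp in \[0, 0.5\].
#'
#' @param ct Tissue concentration, mM, on the time grid.
#' @param aif A `vs_aif`.
#' @param t Time grid, s (length >= 4).
#' @param lower,upper Length-3 bounds for `c(ktrans, ve, vp)`.
#' @return Tibble row: `ktrans`, `ve`, `vp`, `rmse`, `converged`, `flag`.
#'   A flat zero curve returns `ktrans = 0`, `vp = 0`, `ve = NA`
#'   (unidentifiable); non-convergence returns `NA` sentinels with
#'   `converged = FALSE`.
#' @export
fit_etm_voxel <- function(ct, aif, t,
                          lower = c(0, 1e-3, 0), upper = c(2, 1, 0.5)) {
  if (length(ct) != length(t)) abort("`ct` and `t` must have equal length.")
  if (length(ct) < 4L) abort("Need at least 4 time points.")
  cp <- eval_aif(aif, t)
  if (all(abs(ct) < .Machine$double.eps^0.5)) {
    return(tibble::tibble(ktrans = 0, ve = NA_real_, vp = 0, rmse = 0,
                          converged = TRUE, flag = "ve_unidentifiable"))
  }
  tm <- t / 60
  init <- etm_linear_init(ct, cp, tm)
  if (is.null(init)) init <- (lower + upper) / 2
  init <- pmin(pmax(init, lower + c(1e-6, 1e-6, 0)), upper - 1e-6)
  names(init) <- c("ktrans", "ve", "vp")
  resid_fn <- function(p) etm_forward(p[1], p[2], p[3], aif, t) - ct
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower + c(0, 0, 0), upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- fit$par
    rmse <- sqrt(mean(resid_fn(p)^2))
    return(tibble::tibble(ktrans = p[[1]], ve = p[[2]], vp = p[[3]],
                          rmse = rmse, converged = TRUE, flag = NA_character_))
  }
  obj <- function(p) sum(resid_fn(p)^2)
  fit2 <- tryCatch(
    optim(init, obj, method = "L-BFGS-B",
          lower = lower + c(0, 1e-6, 0), upper = upper),
    error = function(e) NULL
  )
  if (is.null(fit2)) {
    return(tibble::tibble(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                          rmse = NA_real_, converged = FALSE,
                          flag = "fit_failed"))
  }
  tibble::tibble(ktrans = fit2$par[[1]], ve = fit2$par[[2]],
                 vp = fit2$par[[3]], rmse = sqrt(fit2$value / length(ct)),
                 converged = TRUE, flag = "lbfgsb_fallback")
}

#' Convert a dynamic SPGR signal to concentration
#'
#' Inverts the SPGR equation frame-by-frame for `T1(t)` using the pre-contrast
#' baseline signal and T10, then
#' `C(t) = (1/T1(t) - 1/T10) / r1`. Signals outside the invertible SPGR range
#' are clipped and flagged.
#'
#' @param s Signal time course (same length as `acquisition$time_grid`).
#' @param t10 Pre-contrast T1, s.
#' @param acquisition An [acquisition_params()]; the dynamic flip angle and TR
#'   are used.
#' @param s_pre Optional baseline signal; default mean over the baseline
#'   frames.
#' @return List with `concentration` (mM) and `n_clipped`.
#' @export
concentration_from_signal <- function(s, t10, acquisition, s_pre = NULL) {
  if (!inherits(acquisition, "vs_acquisition")) {
    abort("`acquisition` must be built with `acquisition_params()`.")
  }
  check_number(t10, "t10", lower = 0, allow_equal_lower = FALSE)
  s_pre <- s_pre %||% mean(s[seq_len(acquisition$baseline_frames)])
  if (!is.finite(s_pre) || s_pre <= 0) abort("Baseline signal must be positive.")
  a <- acquisition$dce_flip * pi / 180
  TR <- acquisition$TR
  E10 <- exp(-TR / t10)
  m0 <- s_pre * (1 - cos(a) * E10) / (sin(a) * (1 - E10))
  E1 <- (m0 * sin(a) - s) / (m0 * sin(a) - s * cos(a))
  bad <- !is.finite(E1) | E1 <= 0 | E1 >= 1
  eps <- 1e-12
  E1 <- pmin(pmax(E1, eps), 1 - eps)
  t1 <- -TR / log(E1)
  conc <- (1 / t1 - 1 / t10) / acquisition$r1
  list(concentration = conc, n_clipped = sum(bad))
}

#' Fit extended Tofts parameter maps over a masked volume
#'
#' Converts each masked voxel's dynamic signal to concentration and fits the
#' ETM, producing Ktrans, ve, vp and fit-RMSE maps. Voxels outside the mask
#' hold `NA`.
#'
#' @param dce 4D array (x, y, z, time).
#' @param mask Binary 3D array (nonempty).
#' @param acquisition An [acquisition_params()].
#' @param aif A `vs_aif`.
#' @param t10 Pre-contrast T1 map (3D array) or a scalar, s.
#' @return A `vs_parameter_maps` list: `ktrans`, `ve`, `vp`, `rmse` (arrays),
#'   `mask`, `converged` (logical array), `n_flagged`.
#' @export
fit_etm_map <- function(dce, mask, acquisition, aif, t10 = 1.4) {
  if (length(dim(dce)) != 4L) abort("`dce` must be a 4D array (x, y, z, t).")
  check_binary_array(mask, "mask")
  if (!all(dim(dce)[1:3] == dim(mask))) {
    abort("`mask` must match the spatial grid of `dce`.")
  }
  idx <- which(mask > 0)
  if (!length(idx)) abort("`mask` is empty.")
  nvox <- prod(dim(mask))
  nt <- dim(dce)[4]
  dce_mat <- matrix(dce, nrow = nvox, ncol = nt)
  t10_vec <- if (is.array(t10)) t10[idx] else rep(t10, length(idx))
  shape <- function() array(NA_real_, dim(mask))
  maps <- list(ktrans = shape(), ve = shape(), vp = shape(), rmse = shape())
  converged <- array(NA, dim(mask))
  n_flagged <- 0L
  tg <- acquisition$time_grid
  for (j in seq_along(idx)) {
    v <- idx[j]
    conc <- concentration_from_signal(dce_mat[v, ], t10_vec[j], acquisition)
    fit <- fit_etm_voxel(conc$concentration, aif, tg)
    maps$ktrans[v] <- fit$ktrans
    maps$ve[v] <- fit$ve
    maps$vp[v] <- fit$vp
    maps$rmse[v] <- fit$rmse
    converged[v] <- fit$converged
    if (!is.na(fit$flag)) n_flagged <- n_flagged + 1L
  }
  structure(list(ktrans = maps$ktrans, ve = maps$ve, vp = maps$vp,
                 rmse = maps$rmse, mask = mask, converged = converged,
                 n_flagged = n_flagged),
            class = "vs_parameter_maps")
}
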