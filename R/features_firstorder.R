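# First-order intensity statistics (18 features). Raw (continuous) ROI
# intensities are used for the moment/percentile features; the histogram
# features (entropy, uniformity) use the discretized levels.

fo_feature_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
    "mean", "median", "iqr", "range", "mad", "robust_mad", "rms", "skewness",
    "kurtosis", "variance", "uniformity")
}

#' First-order radiomic features
#'
#' The 18 standard first-order statistics of the ROI intensity distribution.
#' Entropy and uniformity are computed on the discretized gray levels; all
#' other features use the raw intensities. Skewness and kurtosis use
#' population moments (kurtosis is not excess-corrected); a constant ROI gives
#' 0 for both.
#'
#' @param values Numeric vector of raw ROI intensities (>= 1 voxel).
#' @param levels Integer vector of discretized gray levels for the same
#'   voxels.
#' @param voxel_volume Voxel volume in mm^3 (for total energy).
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(values, levels, voxel_volume = 1) {
  if (!length(values)) abort("Empty ROI.")
  if (length(values) != length(levels)) {
    abort("`values` and `levels` must have equal length.")
  }
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inner <- values[values >= q[1] & values <= q[5]]
  p <- tabulate(levels) / n
  p <- p[p > 0]
  c(
    energy = sum(values^2),
    total_energy = voxel_volume * sum(values^2),
    entropy = -sum(p * log2(p)),
    minimum = min(values),
    p10 = q[1],
    p90 = q[5],
    maximum = max(values),
    mean = mu,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(values) - min(values),
    mad = mean(abs(values - mu)),
    robust_mad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    rms = sqrt(mean(values^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2)
  )
}
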