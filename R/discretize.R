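# Fixed-bin-width gray-level discretization. The bin width is modality
# dependent: the mean ROI intensity range over the TRAINING patients divided
# by the scaling hyper-parameter n_bins. No clipping, truncation or outlier
# exclusion is applied before discretization.

#' Fit modality-dependent bin widths on a training set
#'
#' For each channel, the bin width is the mean (over training patients) of the
#' within-ROI intensity range, divided by `n_bins`. Widths must be fitted on
#' training patients only and then applied unchanged to validation patients.
#'
#' @param images List of per-patient channel lists (each a 3D array), or a
#'   single list of 3D arrays for a one-channel fit.
#' @param masks List of binary 3D arrays, one per patient.
#' @param n_bins Scaling hyper-parameter (>= 2).
#' @return A `vs_bin_widths` tibble with columns `channel`, `mean_range`,
#'   `width`.
#' @export
fit_bin_widths <- function(images, masks, n_bins = 32) {
  check_number(n_bins, "n_bins", lower = 2)
  if (!length(images)) abort("Need at least one training patient.")
  if (is.array(images[[1]])) images <- lapply(images, function(x) list(channel = x))
  channels <- names(images[[1]])
  ranges <- purrr::map_dfr(seq_along(images), function(i) {
    idx <- which(masks[[i]] > 0)
    if (!length(idx)) {
      warn(sprintf("Patient %d has an empty ROI; skipped in bin-width fit.", i))
      return(tibble::tibble())
    }
    purrr::map_dfr(channels, function(ch) {
      v <- images[[i]][[ch]][idx]
      tibble::tibble(channel = ch, range = max(v) - min(v))
    })
  })
  widths_from_ranges(ranges, n_bins)
}

# ranges: tibble(channel, range) with one row per (patient, channel).
widths_from_ranges <- function(ranges, n_bins) {
  out <- dplyr::summarise(dplyr::group_by(ranges, .data$channel),
                          mean_range = mean(.data$range), .groups = "drop")
  out$width <- out$mean_range / n_bins
  if (any(out$width <= 0)) {
    abort("Nonpositive mean intensity range; cannot derive a bin width.")
  }
  class(out) <- c("vs_bin_widths", class(out))
  out
}

#' Discretize an image to integer gray levels
#'
#' Min-anchored fixed-bin-width discretization:
#' `level = floor((x - min_ROI) / width) + 1`. Levels start at 1; extreme
#' values are never clipped. Shifting all intensities by a constant leaves the
#' levels unchanged.
#'
#' @param image Numeric 3D array.
#' @param mask Binary 3D array; voxels outside the mask get `NA`.
#' @param width Positive bin width in intensity units.
#' @return Integer-level 3D array (`NA` outside the mask) with attribute
#'   `n_levels` = maximum occupied level.
#' @export
discretize <- function(image, mask, width) {
  check_number(width, "width", lower = 0, allow_equal_lower = FALSE)
  check_binary_array(mask, "mask")
  if (!all(dim(image) == dim(mask))) abort("`image` and `mask` grids differ.")
  idx <- which(mask > 0)
  if (!length(idx)) abort("`mask` is empty.")
  out <- array(NA_integer_, dim(mask))
  v <- image[idx]
  lev <- as.integer(floor((v - min(v)) / width) + 1)
  out[idx] <- lev
  attr(out, "n_levels") <- max(lev)
  out
}
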