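# ROI conditioning: intensity normalization, cyst removal, morphological
# erosion and nearest-neighbour mask projection. Masks are plain binary 3D
# arrays; voxel spacing (mm) and provenance travel as attributes.

#' Construct an ROI mask object
#'
#' Wraps a binary 3D array with voxel spacing and provenance metadata. All ROI
#' operations in the package accept either a plain binary array or a mask
#' built with this constructor.
#'
#' @param mask Binary (0/1) 3D array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param provenance Character tag describing how the mask was obtained
#'   (`"raw"`, `"cyst_removed"`, `"eroded"`, ...).
#' @return The mask array with `spacing` and `provenance` attributes, class
#'   `vs_mask`.
#' @export
vs_mask <- function(mask, spacing = c(1, 1, 1), provenance = "raw") {
  check_binary_array(mask)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes (mm).")
  }
  structure(mask, spacing = as.numeric(spacing), provenance = provenance,
            class = c("vs_mask", class(mask)))
}

mask_spacing <- function(mask, default = c(1, 1, 1)) {
  attr(mask, "spacing") %||% default
}

#' Z-score normalize an image
#'
#' Centers and scales image intensities so the reference region has mean 0 and
#' standard deviation 1. By default the reference region is the nonzero
#' support of the image; a binary mask can restrict it (e.g. to the tumor
#' ROI).
#'
#' @param image Numeric 3D array.
#' @param reference Optional binary array (same dimensions) selecting the
#'   reference region. `NULL` uses all voxels with nonzero intensity.
#' @return Normalized array of the same dimensions.
#' @export
zscore_normalize <- function(image, reference = NULL) {
  if (!is.array(image)) abort("`image` must be an array.")
  if (is.null(reference)) {
    ref_idx <- which(image != 0)
  } else {
    if (!all(dim(reference) == dim(image))) {
      abort("`reference` must match the image dimensions.")
    }
    ref_idx <- which(reference > 0)
  }
  if (length(ref_idx) < 2L) {
    abort("Reference region must contain more than one voxel.")
  }
  vals <- image[ref_idx]
  mu <- mean(vals)
  sigma <- sd(vals)
  if (!is.finite(sigma) || sigma == 0) {
    abort("Reference region has zero intensity variance; cannot Z-score normalize.")
  }
  (image - mu) / sigma
}

#' Remove cystic components from a tumor ROI
#'
#' Cystic tumor components lack cellularity and microvascularity and are
#' excluded from the perfusion ROI: the result is the voxelwise set difference
#' `roi \ cysts`.
#'
#' @param roi,cysts Binary 3D arrays on the same grid. `cysts` may be empty.
#' @return The cyst-free mask (provenance `"cyst_removed"`). A fully cystic
#'   ROI yields an empty mask with attribute `degenerate = TRUE` and a
#'   warning.
#' @export
remove_cysts <- function(roi, cysts) {
  check_binary_array(roi, "roi")
  check_binary_array(cysts, "cysts")
  if (!all(dim(roi) == dim(cysts))) {
    abort("`roi` and `cysts` must be on the same grid.")
  }
  out <- roi * (1 - cysts)
  res <- vs_mask(out, spacing = mask_spacing(roi), provenance = "cyst_removed")
  if (sum(out) == 0) {
    warn("Cyst removal left an empty ROI (cysts cover the whole tumor).")
    attr(res, "degenerate") <- TRUE
  }
  res
}

#' Erode a mask with a cross-shaped structuring element
#'
#' Binary erosion with the 3x3 4-connected cross, applied slice-wise
#' (in-plane) by default: a voxel survives only if it and its four in-plane
#' neighbours are inside the mask. This trims the ROI contour so that voxels
#' affected by partial-volume effects at the lower DCE resolution are
#' excluded. Set `planes = FALSE` for 3D 6-connected erosion.
#'
#' @param roi Binary 3D array.
#' @param planes If `TRUE` (default) erode each axial slice independently with
#'   the 2D cross; if `FALSE` use the 3D 6-connected cross.
#' @return Eroded mask (provenance `"eroded"`), always a subset of the input.
#' @export
erode_cross <- function(roi, planes = TRUE) {
  check_binary_array(roi, "roi")
  dm <- dim(roi)
  pad <- array(0, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- roi
  ix <- 2:(dm[1] + 1L); iy <- 2:(dm[2] + 1L); iz <- 2:(dm[3] + 1L)
  keep <- pad[ix, iy, iz, drop = FALSE] *
    pad[ix - 1L, iy, iz, drop = FALSE] *
    pad[ix + 1L, iy, iz, drop = FALSE] *
    pad[ix, iy - 1L, iz, drop = FALSE] *
    pad[ix, iy + 1L, iz, drop = FALSE]
  if (!planes) {
    keep <- keep *
      pad[ix, iy, iz - 1L, drop = FALSE] *
      pad[ix, iy, iz + 1L, drop = FALSE]
  }
  dim(keep) <- dm
  vs_mask(keep, spacing = mask_spacing(roi), provenance = "eroded")
}

#' Describe a sampling grid
#'
#' Axis-aligned grid descriptor used by [project_mask()]: voxel spacing (mm),
#' world origin of the first voxel center (mm) and grid dimensions.
#'
#' @param spacing,origin Numeric length-3.
#' @param dim Integer length-3 grid size.
#' @return A `vs_grid` list.
#' @export
vs_grid <- function(spacing, origin = c(0, 0, 0), dim) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) abort("Grid spacing must be positive.")
  if (length(dim) != 3L || any(dim < 1)) abort("Grid `dim` must be three positive sizes.")
  structure(list(spacing = as.numeric(spacing), origin = as.numeric(origin),
                 dim = as.integer(dim)), class = "vs_grid")
}

#' Project a mask onto another sampling grid
#'
#' Nearest-neighbour resampling of a binary mask from its source grid onto a
#' target grid (e.g. from the T2 grid onto the DCE parameter-map grid). Both
#' grids must be axis-aligned; the registration transform itself is assumed
#' already applied (identical world frame).
#'
#' @param roi Binary 3D array on `source_grid`.
#' @param source_grid,target_grid [vs_grid()] descriptors.
#' @return Binary mask on the target grid.
#' @export
project_mask <- function(roi, source_grid, target_grid) {
  check_binary_array(roi, "roi")
  if (!inherits(source_grid, "vs_grid") || !inherits(target_grid, "vs_grid")) {
    abort("Grids must be built with `vs_grid()`.")
  }
  if (!all(dim(roi) == source_grid$dim)) {
    abort("`roi` dimensions do not match `source_grid$dim`.")
  }
  if (identical(source_grid, target_grid)) {
    return(vs_mask(roi, spacing = source_grid$spacing,
                   provenance = attr(roi, "provenance") %||% "raw"))
  }
  src_idx_axis <- function(axis) {
    world <- target_grid$origin[axis] +
      (seq_len(target_grid$dim[axis]) - 1) * target_grid$spacing[axis]
    idx <- round((world - source_grid$origin[axis]) / source_grid$spacing[axis]) + 1
    as.integer(idx)
  }
  ii <- src_idx_axis(1); jj <- src_idx_axis(2); kk <- src_idx_axis(3)
  out <- array(0, target_grid$dim)
  okx <- ii >= 1 & ii <= source_grid$dim[1]
  oky <- jj >= 1 & jj <= source_grid$dim[2]
  okz <- kk >= 1 & kk <= source_grid$dim[3]
  out[okx, oky, okz] <- roi[ii[okx], jj[oky], kk[okz]]
  vs_mask(out, spacing = target_grid$spacing, provenance = "resampled")
}
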