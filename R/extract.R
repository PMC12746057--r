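# Per-patient feature vector assembly: 101 features (18 first-order, 8 shape,
# 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) per channel, over the four
# channels T2, Ktrans, ve, vp -> 404 named values. Shape features depend only
# on the mask and are computed once, then replicated per channel to keep the
# 4 x 101 accounting.

vs_channels <- function() c("t2", "ktrans", "ve", "vp")

#' Radiomic feature name manifest
#'
#' The frozen ordering of the 404-element feature vector:
#' channel-major (`t2`, `ktrans`, `ve`, `vp`), family order first-order,
#' shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM within each channel. Names are
#' `<channel>_<family>_<feature>`.
#'
#' @param channels Channels to include (default all four).
#' @return Tibble with columns `name`, `channel`, `family`, `feature`.
#' @export
feature_manifest <- function(channels = vs_channels()) {
  fams <- list(
    fo = fo_feature_names(),
    shape = shape_feature_names(),
    glcm = glcm_feature_names(),
    glrlm = glrlm_feature_names(),
    glszm = glszm_feature_names(),
    ngtdm = ngtdm_feature_names(),
    gldm = gldm_feature_names()
  )
  per_channel <- purrr::map_dfr(names(fams), function(f) {
    tibble::tibble(family = f, feature = fams[[f]])
  })
  purrr::map_dfr(channels, function(ch) {
    tibble::tibble(
      name = paste(ch, per_channel$family, per_channel$feature, sep = "_"),
      channel = ch, family = per_channel$family, feature = per_channel$feature
    )
  })
}

# 101 features of one channel given raw masked values and the level vector
# (ROI voxels, same order as ctx$idx); `shape` is the per-patient shape
# vector to replicate.
channel_features_ctx <- function(values, lev, ng, ctx, shape, voxel_volume) {
  c(
    setNames(first_order_features(values, lev, voxel_volume),
             paste0("fo_", fo_feature_names())),
    setNames(shape, paste0("shape_", shape_feature_names())),
    setNames(glcm_features_ctx(lev, ng, ctx),
             paste0("glcm_", glcm_feature_names())),
    setNames(glrlm_features_ctx(lev, ng, ctx),
             paste0("glrlm_", glrlm_feature_names())),
    setNames(glszm_features_ctx(lev, ng, ctx),
             paste0("glszm_", glszm_feature_names())),
    setNames(ngtdm_features_ctx(lev, ng, ctx),
             paste0("ngtdm_", ngtdm_feature_names())),
    setNames(gldm_features_ctx(lev, ng, ctx),
             paste0("gldm_", gldm_feature_names()))
  )
}

#' Extract the full radiomic feature vector of one patient
#'
#' Discretizes each channel with its modality-specific bin width and computes
#' the 101 features per channel, concatenated in the [feature_manifest()]
#' order (404 values for the default four channels).
#'
#' @param channels Named list of 3D arrays; must contain `t2`, `ktrans`, `ve`,
#'   `vp` (or the subset named in `use_channels`).
#' @param mask Binary 3D array, the conditioned tumor ROI.
#' @param widths A `vs_bin_widths` table from [fit_bin_widths()] (or a named
#'   numeric vector of widths per channel).
#' @param spacing Voxel spacing, mm.
#' @param use_channels Channels to extract (default all four).
#' @return A one-row tibble of named features.
#' @export
extract_features <- function(channels, mask, widths, spacing = c(1, 1, 1),
                             use_channels = vs_channels()) {
  missing_ch <- setdiff(use_channels, names(channels))
  if (length(missing_ch)) {
    abort(paste0("Missing channel(s): ", paste(missing_ch, collapse = ", ")))
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (inherits(widths, "data.frame")) {
    w <- setNames(widths$width, widths$channel)
  } else {
    w <- widths
  }
  missing_w <- setdiff(use_channels, names(w))
  if (length(missing_w)) {
    abort(paste0("No bin width for channel(s): ",
                 paste(missing_w, collapse = ", ")))
  }
  idx <- which(mask > 0)
  if (!length(idx)) abort("Empty ROI mask.")
  shp <- shape_features(mask, spacing)
  voxvol <- prod(spacing)
  ctx <- mask_context(array(as.numeric(mask > 0), dim(mask)))
  out <- purrr::map(use_channels, function(ch) {
    img <- channels[[ch]]
    v <- img[idx]
    lev <- as.integer(floor((v - min(v)) / w[[ch]]) + 1)
    feats <- channel_features_ctx(v, lev, max(lev), ctx, shp, voxvol)
    setNames(feats, paste(ch, names(feats), sep = "_"))
  })
  tibble::as_tibble(as.list(unlist(out)))
}

#' Precompute a cohort feature source
#'
#' Caches everything feature extraction needs per patient (masked channel
#' intensities, ROI ranges, shape features, mask geometry) so that fold-wise
#' re-extraction under fold-specific bin widths only recomputes the
#' discretization-dependent features.
#'
#' @param cohort A cohort from [generate_cohort()] (or a list of patient
#'   records with `id`, `channels`, `roi_mask`, `spacing`).
#' @return A `vs_feature_source` object.
#' @export
precompute_features <- function(cohort) {
  patients <- purrr::map(cohort$patients, function(p) {
    mask <- p$roi_mask
    idx <- which(mask > 0)
    spacing <- mask_spacing(mask, default = cohort$config$grid_spacing %||% c(1, 1, 1))
    vals <- purrr::map(p$channels, ~ .x[idx])
    ranges <- purrr::map_dbl(vals, ~ max(.x) - min(.x))
    list(id = p$id, idx = idx, spacing = spacing,
         values = vals, ranges = ranges,
         ctx = mask_context(array(as.numeric(mask > 0), dim(mask))),
         shape = shape_features(mask, spacing),
         voxvol = prod(spacing))
  })
  structure(list(patients = patients,
                 ids = purrr::map_chr(cohort$patients, "id")),
            class = "vs_feature_source")
}

# Extract the cohort feature table under given per-channel widths, using a
# precomputed source. Returns tibble: id + 404 feature columns.
extract_cohort_features <- function(source, widths,
                                    use_channels = vs_channels()) {
  stopifnot(inherits(source, "vs_feature_source"))
  w <- if (inherits(widths, "data.frame")) {
    setNames(widths$width, widths$channel)
  } else widths
  rows <- purrr::map(source$patients, function(p) {
    feats <- purrr::map(use_channels, function(ch) {
      v <- p$values[[ch]]
      lev <- as.integer(floor((v - min(v)) / w[[ch]]) + 1)
      out <- channel_features_ctx(v, lev, max(lev), p$ctx, p$shape, p$voxvol)
      setNames(out, paste(ch, names(out), sep = "_"))
    })
    c(id = p$id, as.list(unlist(feats)))
  })
  purrr::map_dfr(rows, tibble::as_tibble)
}
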