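# NIfTI-1 / CSV / JSON persistence for synthetic cohorts.

#' Write a cohort to disk
#'
#' Per patient: T2 and parameter-map volumes plus ROI/cyst masks as NIfTI-1,
#' follow-up volumes in one long CSV, a cohort manifest CSV and the
#' configuration as JSON.
#'
#' @param cohort A `vs_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble augmented with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "vs_cohort")) abort("`cohort` must be a `vs_cohort`.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$config$grid_spacing
  rows <- purrr::map_dfr(cohort$patients, function(p) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    paths <- c(t2 = "t2.nii.gz", ktrans = "ktrans.nii.gz", ve = "ve.nii.gz",
               vp = "vp.nii.gz", roi = "roi.nii.gz", cyst = "cyst.nii.gz")
    vols <- c(p$channels, list(roi = unclass(p$roi_mask), cyst = p$cyst_mask))
    for (nm in names(paths)) {
      img <- RNifti::asNifti(vols[[nm]], pixdim = rep(sp, 3))
      RNifti::writeNifti(img, file.path(pdir, paths[[nm]]))
    }
    tibble::tibble(id = p$id, dir = pdir)
  })
  fu <- purrr::map_dfr(cohort$patients, function(p) {
    dplyr::bind_cols(tibble::tibble(id = p$id), p$followups)
  })
  utils::write.csv(fu, file.path(dir, "followup_volumes.csv"),
                   row.names = FALSE)
  manifest <- dplyr::left_join(cohort$manifest, rows, by = "id")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$class_effects <- as.data.frame(cfg$class_effects)
  cfg$acquisition <- unclass(cfg$acquisition)
  cfg$threshold <- list(a = cfg$threshold$a, b = cfg$threshold$b,
                        floor = cfg$threshold$floor,
                        ceiling = cfg$threshold$ceiling)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort's images back from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `manifest` (tibble), `followups` (tibble) and a
#'   `load_patient(id)` function returning the channel arrays and masks.
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  )
  followups <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "followup_volumes.csv"),
                    stringsAsFactors = FALSE)
  )
  load_patient <- function(id) {
    pdir <- manifest$dir[match(id, manifest$id)]
    rd <- function(f) {
      img <- RNifti::readNifti(file.path(pdir, f))
      array(as.numeric(img), dim(img))
    }
    list(
      channels = list(t2 = rd("t2.nii.gz"), ktrans = rd("ktrans.nii.gz"),
                      ve = rd("ve.nii.gz"), vp = rd("vp.nii.gz")),
      roi_mask = rd("roi.nii.gz"), cyst_mask = rd("cyst.nii.gz")
    )
  }
  list(manifest = manifest, followups = followups,
       load_patient = load_patient)
}
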