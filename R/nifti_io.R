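#' Write a tumor volume (image + masks) as NIfTI
#'
#' @param vol a `tumor_volume`.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return invisibly, the written file paths.
#' @export
write_volume_nifti <- function(vol, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  mk <- function(arr) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- vol$spacing
    im
  }
  paths <- c(image = file.path(dir, paste0(vol$patient_id, "_image", ext)),
             mask = file.path(dir, paste0(vol$patient_id, "_mask", ext)))
  RNifti::writeNifti(mk(vol$image), paths["image"])
  RNifti::writeNifti(mk(vol$mask), paths["mask"])
  if (!is.null(vol$repeat_masks)) {
    for (rn in names(vol$repeat_masks)) {
      p <- file.path(dir, paste0(vol$patient_id, "_mask_", rn, ext))
      RNifti::writeNifti(mk(vol$repeat_masks[[rn]]), p)
      paths[paste0("mask_", rn)] <- p
    }
  }
  invisible(paths)
}

#' Read an image + mask pair from NIfTI files
#'
#' @param image_path,mask_path file paths (`.nii` or `.nii.gz`).
#' @param patient_id optional identifier attached to the result.
#' @return a `tumor_volume` (without repeat masks unless supplied).
#' @param repeat_paths optional named character vector of repeat-mask paths.
#' @export
read_volume_nifti <- function(image_path, mask_path, patient_id = NULL,
                              repeat_paths = NULL) {
  im <- RNifti::readNifti(image_path)
  mk <- RNifti::readNifti(mask_path)
  if (!all(dim(im) == dim(mk))) stop("image and mask grids differ")
  spacing <- attr(RNifti::niftiHeader(im), "pixdim")[2:4] %||%
    RNifti::pixdim(im)[1:3]
  reps <- NULL
  if (!is.null(repeat_paths))
    reps <- lapply(repeat_paths, function(p)
      array(as.integer(as.array(RNifti::readNifti(p)) > 0.5), dim(im)))
  structure(list(image = as.array(im) * 1.0,
                 mask = array(as.integer(as.array(mk) > 0.5), dim(im)),
                 spacing = as.numeric(RNifti::pixdim(im)[1:3]),
                 repeat_masks = reps,
                 patient_id = patient_id %||% sub("\\.nii(\\.gz)?$", "", basename(image_path))),
            class = "tumor_volume")
}

#' Write a habitat label map as NIfTI
#'
#' @param habitat a `habitat_map`.
#' @param path output file path.
#' @param spacing voxel spacing to record.
#' @export
write_labels_nifti <- function(habitat, path, spacing = c(1, 1, 1)) {
  im <- RNifti::asNifti(habitat$labels)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}
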