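#' Preprocessing specification for feature extraction
#'
#' @param target_spacing numeric triple, mm; images are resampled to this
#'   spacing (trilinear) and masks/label maps with nearest neighbour.
#' @param n_gray_levels number of gray levels for fixed-bin-count
#'   discretization of masked intensities.
#' @param min_subregion_voxels subregions smaller than this are flagged and
#'   their feature rows excluded downstream.
#' @param filters optional image filters to extend the feature bank; currently
#'   `"log"` (Laplacian of Gaussian) is supported.
#' @param log_sigma sigma (mm) of the LoG filter.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_spacing = c(1, 1, 1), n_gray_levels = 25L,
                            min_subregion_voxels = 10L, filters = character(0),
                            log_sigma = 1) {
  stopifnot(length(target_spacing) == 3, all(target_spacing > 0),
            n_gray_levels >= 2)
  if (length(filters))
    filters <- match.arg(filters, c("log"), several.ok = TRUE)
  structure(list(target_spacing = as.numeric(target_spacing),
                 n_gray_levels = as.integer(n_gray_levels),
                 min_subregion_voxels = as.integer(min_subregion_voxels),
                 filters = filters, log_sigma = log_sigma),
            class = "preprocess_spec")
}

#' Resample a volume (and its masks) to a target voxel spacing
#'
#' Intensities are interpolated trilinearly; the mask, repeat masks and any
#' habitat label map are resampled with nearest-neighbour interpolation so
#' they stay integer-valued.
#'
#' @param vol a `tumor_volume` (needs `image`, `spacing`, `mask`; optional
#'   `repeat_masks`).
#' @param target_spacing numeric triple (mm).
#' @param labels optional 3-D integer label array on the same grid.
#' @return list with the resampled `vol` (spacing updated) and, if given,
#'   resampled `labels`.
#' @export
resample_volume <- function(vol, target_spacing = c(1, 1, 1), labels = NULL) {
  if (is.null(vol$spacing) || any(!is.finite(vol$spacing)))
    stop("volume has no voxel spacing metadata")
  sp <- as.numeric(vol$spacing)
  tg <- as.numeric(target_spacing)
  if (isTRUE(all.equal(sp, tg))) {
    return(list(vol = vol, labels = labels))
  }
  out <- vol
  out$image <- resample3d(vol$image, sp, tg, "linear")
  out$mask <- array(as.integer(resample3d(vol$mask, sp, tg, "nearest")),
                    dim(out$image))
  if (!is.null(vol$repeat_masks))
    out$repeat_masks <- lapply(vol$repeat_masks, function(m)
      array(as.integer(resample3d(m, sp, tg, "nearest")), dim(out$image)))
  out$spacing <- tg
  new_labels <- if (!is.null(labels))
    array(as.integer(resample3d(labels, sp, tg, "nearest")), dim(out$image))
  list(vol = out, labels = new_labels)
}

#' Fixed-bin-count gray-level discretization
#'
#' Maps masked intensities to integer levels `1..n_levels` over the region's
#' own min-max range: `floor(n * (x - min) / (max - min)) + 1`, clamped to
#' `[1, n_levels]`. A constant region maps entirely to level 1.
#'
#' @param x numeric vector of masked intensities.
#' @param n_levels number of gray levels (default 25).
#' @return integer vector of levels in `1..n_levels`.
#' @export
discretize_gray <- function(x, n_levels = 25L) {
  if (length(x) == 0) stop("mask is empty")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  g <- floor(n_levels * (x - rng[1]) / (rng[2] - rng[1])) + 1
  as.integer(pmin(pmax(g, 1L), n_levels))
}

# Laplacian-of-Gaussian filtered image (difference of the smoothed image and
# its further-smoothed version approximates -LoG up to scale; we use the
# discrete 6-neighbour Laplacian of the Gaussian-smoothed image).
log_filter3d <- function(image, sigma) {
  sm <- smooth3d(image, sigma)
  lap <- -6 * sm
  for (dd in 1:3) for (o in c(-1L, 1L)) lap <- lap + shift3d(sm, o, dd)
  lap
}
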