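#' Extract the full feature bank from one region
#'
#' Discretizes the masked intensities to `n_levels` and computes the
#' first-order, shape, GLCM, GLRLM and GLSZM families (76 features). With the
#' LoG filter enabled, the intensity and texture families are re-extracted
#' from the filtered image with a `log_` prefix.
#'
#' @param image 3-D numeric array (already resampled).
#' @param region_mask 3-D binary array for this region.
#' @param spacing voxel spacing (mm).
#' @param spec a [preprocess_spec()].
#' @return named numeric vector.
#' @export
region_features <- function(image, region_mask, spacing, spec = preprocess_spec()) {
  nvox <- sum(region_mask == 1)
  if (nvox == 0) stop("empty region")
  bank <- function(img) {
    x <- img[region_mask == 1]
    lv <- array(0L, dim(img))
    lv[region_mask == 1] <- discretize_gray(x, spec$n_gray_levels)
    fo <- first_order_features(x, spec$n_gray_levels)
    gl <- glcm_features(lv, spec$n_gray_levels)
    rl <- glrlm_features(lv, spec$n_gray_levels)
    sz <- glszm_features(lv, spec$n_gray_levels)
    c(stats::setNames(fo, paste0("fo_", names(fo))),
      stats::setNames(gl, paste0("glcm_", names(gl))),
      stats::setNames(rl, paste0("glrlm_", names(rl))),
      stats::setNames(sz, paste0("glszm_", names(sz))))
  }
  sh <- shape_features(region_mask, spacing)
  feats <- c(bank(image), stats::setNames(sh, paste0("shape_", names(sh))))
  if ("log" %in% spec$filters) {
    fi <- log_filter3d(image, spec$log_sigma / mean(spacing))
    lf <- bank(fi)
    feats <- c(feats, stats::setNames(lf, paste0("log_", names(lf))))
  }
  feats
}

#' Extract features for VOI_e and every habitat subregion of one patient
#'
#' The volume is resampled to the target spacing (image trilinear, masks and
#' labels nearest-neighbour), then the whole-tumor region (`VOIe`) and each
#' habitat subregion (`VOI1`, `VOI2`, ...) receive the identical feature bank.
#' Subregions smaller than `spec$min_subregion_voxels` are flagged; flagged
#' rows carry `NA` features and are excluded downstream.
#'
#' @param vol a `tumor_volume`.
#' @param habitat a `habitat_map` from [segment_habitats()] (aligned with
#'   `vol`'s grid), or `NULL` to extract `VOIe` only.
#' @param spec a [preprocess_spec()].
#' @param mask optional alternative delineation (3-D binary array on `vol`'s
#'   grid) replacing `vol$mask`, used for repeat-delineation extraction.
#' @return data.frame with columns `patient_id`, `region`, `n_voxels`,
#'   `flagged`, then one column per feature.
#' @export
extract_features <- function(vol, habitat = NULL, spec = preprocess_spec(),
                             mask = NULL) {
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(vol$image))) stop("mask grid misaligned with image")
    vol$mask <- mask
  }
  labels <- NULL
  if (!is.null(habitat)) {
    if (!all(dim(habitat$labels) == dim(vol$image)))
      stop("habitat label grid misaligned with image")
    labels <- habitat$labels
  }
  rs <- resample_volume(vol, spec$target_spacing, labels)
  vol <- rs$vol; labels <- rs$labels
  regions <- list(VOIe = vol$mask)
  if (!is.null(labels)) {
    ks <- sort(unique(labels[labels > 0]))
    for (k in ks) {
      m <- array(as.integer(labels == k & vol$mask == 1), dim(vol$mask))
      regions[[paste0("VOI", k)]] <- m
    }
  }
  rows <- list()
  feat_names <- NULL
  for (rn in names(regions)) {
    m <- regions[[rn]]
    nv <- sum(m)
    flagged <- nv < spec$min_subregion_voxels
    f <- NULL
    if (!flagged) {
      # degenerate subregions (e.g. scattered voxels with no co-occurring
      # pairs) are flagged rather than fatal, like undersized ones
      f <- tryCatch(region_features(vol$image, m, vol$spacing, spec),
                    error = function(e) {
                      warning("region ", rn, " flagged: ", conditionMessage(e))
                      NULL
                    })
      if (is.null(f)) flagged <- TRUE else feat_names <- names(f)
    }
    rows[[rn]] <- list(n_voxels = nv, flagged = flagged, f = f)
  }
  if (is.null(feat_names)) stop("all regions smaller than min_subregion_voxels")
  df <- do.call(rbind, lapply(names(rows), function(rn) {
    r <- rows[[rn]]
    f <- r$f %||% stats::setNames(rep(NA_real_, length(feat_names)), feat_names)
    cbind(data.frame(patient_id = vol$patient_id %||% "P000", region = rn,
                     n_voxels = r$n_voxels, flagged = r$flagged,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f), check.names = FALSE))
  }))
  rownames(df) <- NULL
  df
}

#' Extract features for a whole cohort
#'
#' Runs [segment_habitats()] (if maps are not supplied) and
#' [extract_features()] for every patient.
#'
#' @param cohort a `synthetic_cohort` (or list with `volumes`).
#' @param habitats optional list of `habitat_map`s named by patient.
#' @param spec a [preprocess_spec()].
#' @param k_range,seed passed to [segment_habitats()] when `habitats` is NULL.
#' @return list with `features` (long data.frame) and `habitats`.
#' @export
extract_cohort <- function(cohort, habitats = NULL, spec = preprocess_spec(),
                           k_range = 2:10, seed = 1L) {
  vols <- cohort$volumes
  if (is.null(habitats)) {
    seeds <- fan_seeds(seed, length(vols))
    habitats <- lapply(seq_along(vols), function(i)
      segment_habitats(vols[[i]], k_range = k_range, seed = seeds[i]))
    names(habitats) <- names(vols)
  }
  tabs <- lapply(seq_along(vols), function(i)
    extract_features(vols[[i]], habitats[[i]], spec))
  list(features = do.call(rbind, tabs), habitats = habitats)
}

#' Widen a long feature table to one row per patient
#'
#' Produces columns named `region_family_feature` (e.g. `VOI1_glcm_contrast`).
#' Flagged region rows contribute `NA`s; optionally patients with any flagged
#' region are dropped, mirroring the exclusion of patients whose subregions
#' could not be segmented.
#'
#' @param ft long feature table from [extract_features()].
#' @param drop_flagged drop patients having any flagged region (default TRUE).
#' @return wide data.frame, one row per patient, first column `patient_id`.
#' @export
pivot_features <- function(ft, drop_flagged = TRUE) {
  if (drop_flagged) {
    bad <- unique(ft$patient_id[ft$flagged])
    ft <- ft[!ft$patient_id %in% bad, , drop = FALSE]
  }
  ids <- unique(ft$patient_id)
  feat_cols <- setdiff(names(ft), c("patient_id", "region", "n_voxels", "flagged"))
  regions <- unique(ft$region)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (rg in regions) {
    sub <- ft[ft$region == rg, c("patient_id", feat_cols)]
    m <- sub[match(ids, sub$patient_id), feat_cols, drop = FALSE]
    names(m) <- paste0(rg, "_", feat_cols)
    out <- cbind(out, m)
  }
  rownames(out) <- NULL
  out
}
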