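test_that("resampling honors spacing arithmetic and interpolation contracts", {
  img <- array(rnorm(10^3, 50, 5), c(10, 10, 10))
  mask <- array(0L, c(10, 10, 10)); mask[3:8, 3:8, 3:8] <- 1L
  vol <- list(image = img, mask = mask, spacing = c(2, 2, 2), patient_id = "P")
  out <- resample_volume(vol, c(1, 1, 1))$vol
  expect_equal(dim(out$image), c(20L, 20L, 20L))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_true(all(out$mask %in% c(0L, 1L)))
  # identity when already at target spacing
  vol1 <- list(image = img, mask = mask, spacing = c(1, 1, 1))
  expect_identical(resample_volume(vol1, c(1, 1, 1))$vol$image, img)
  # constant volume stays constant under trilinear interpolation
  volc <- list(image = array(7, c(6, 6, 6)), mask = mask[1:6, 1:6, 1:6],
               spacing = c(2, 2, 2))
  expect_true(all(abs(resample_volume(volc, c(1, 1, 1))$vol$image - 7) < 1e-12))
  expect_error(resample_volume(list(image = img, mask = mask, spacing = NULL)),
               "spacing")
})

test_that("gray-level discretization maps min to 1, max to n_levels", {
  x <- runif(5000)
  g <- discretize_gray(x, 25)
  expect_equal(g[which.min(x)], 1L)
  expect_equal(g[which.max(x)], 25L)
  expect_true(all(g >= 1 & g <= 25))
  # uniform input: each level frequency ~ 1/25
  expect_lt(max(abs(tabulate(g, 25) / length(x) - 1 / 25)), 0.015)
  # constant region: all level 1, downstream features finite
  expect_identical(discretize_gray(rep(3.3, 10), 25), rep(1L, 10))
})

test_that("first-order features match hand arithmetic and invariances", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)    # population variance
  expect_equal(f[["range"]], 3)
  expect_equal(f[["median"]], 2.5)
  # constant region
  fc <- first_order_features(rep(5, 20))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["uniformity"]], 1)
  expect_equal(fc[["skewness"]], 0)
  # homogeneity under scaling
  set.seed(1)
  x <- rnorm(200, 10, 2)
  f1 <- first_order_features(x); f2 <- first_order_features(3 * x)
  expect_equal(f2[["mean"]], 3 * f1[["mean"]])
  expect_equal(f2[["variance"]], 9 * f1[["variance"]])
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("GLCM matches brute-force pair enumeration on a toy grid", {
  lv <- array(0L, c(3, 3, 1))
  lv[, , 1] <- matrix(c(1, 1, 2, 1, 2, 2, 2, 2, 2), 3, byrow = TRUE)
  off <- c(0, 1, 0)
  expect_equal(glcm_matrix(lv, 2, off), oracle_glcm(lv, 2, off))
  # and the derived contrast agrees with the oracle formulas
  P <- glcm_matrix(lv, 2, off)
  expect_equal(unname(.glcm_contrast <- sum((row(P) - col(P))^2 * P / sum(P))),
               unname(oracle_glcm_features(P)[["contrast"]]))
})

test_that("single-gray-level regions give degenerate but exact GLCM features", {
  lv <- array(1L, c(3, 3, 3))
  f <- glcm_features(lv, 4)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["joint_energy"]], 1)
  expect_equal(f[["joint_entropy"]], 0)
  expect_error(glcm_features(array(c(1L, rep(0L, 7)), c(2, 2, 2)), 2),
               "at least 2")
})

test_that("permuting gray levels leaves GLCM entropy unchanged", {
  set.seed(2)
  lv <- random_region(4)
  per <- c(3L, 1L, 4L, 2L)
  lv2 <- lv; lv2[lv > 0] <- per[lv[lv > 0]]
  f1 <- glcm_features(lv, 4); f2 <- glcm_features(lv2, 4)
  expect_equal(f1[["joint_entropy"]], f2[["joint_entropy"]], tolerance = 1e-12)
  expect_equal(f1[["joint_energy"]], f2[["joint_energy"]], tolerance = 1e-12)
})

test_that("run-length features match hand enumeration", {
  # constant 4x1x1 region: one run of length 4 along x, run percentage 1/4
  lv <- array(0L, c(4, 3, 3)); lv[1:4, 2, 2] <- 1L
  P <- glrlm_matrix(lv, 2, c(1, 0, 0))
  expect_equal(P[1, 4], 1)
  expect_equal(sum(P), 1)
  expect_equal(sum(P) / sum(lv > 0), 1 / 4)   # RP in that direction
  # checkerboard along x: all runs length 1, SRE = 1 in that direction
  lv2 <- array(0L, c(6, 1, 1)); lv2[, 1, 1] <- rep(c(1L, 2L), 3)
  P2 <- glrlm_matrix(lv2, 2, c(1, 0, 0))
  expect_equal(ncol(P2), 1L)                  # no run longer than 1
  expect_equal(sum(P2[, 1]), 6)
})

test_that("size-zone matrix counts disjoint constant blobs as zones", {
  lv <- array(0L, c(8, 4, 4))
  lv[1:5, 1, 1] <- 1L          # zone of size 5 at level 1
  lv[c(1, 2, 3), 4, 4] <- 2L   # zone of size 3 at level 2
  P <- glszm_matrix(lv, 2)
  expect_equal(sum(P), 2)      # exactly two zones
  expect_equal(P[1, 5], 1)
  expect_equal(P[2, 3], 1)
})

test_that("texture features equal enumeration oracles on random regions", {
  set.seed(3)
  offs <- offsets13()
  for (rep in 1:5) {
    lv <- random_region(4)
    nv <- sum(lv > 0)
    fg <- glcm_features(lv, 4)
    og <- colMeans(do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
      P <- oracle_glcm(lv, 4, offs[r, ])
      if (sum(P) == 0) return(NULL)
      oracle_glcm_features(P)
    })))
    expect_equal(fg, og[names(fg)], tolerance = 1e-10)
    fr <- glrlm_features(lv, 4)
    or <- colMeans(do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
      oracle_size_features(oracle_glrlm(lv, 4, offs[r, ]), nv))))
    expect_equal(unname(fr), unname(or), tolerance = 1e-10)
    fz <- glszm_features(lv, 4)
    oz <- oracle_size_features(oracle_glszm(lv, 4), nv)
    expect_equal(unname(fz), unname(oz), tolerance = 1e-10)
  }
})

test_that("shape features match hand arithmetic on canonical solids", {
  m1 <- array(0L, c(3, 3, 3)); m1[2, 2, 2] <- 1L
  s1 <- shape_features(m1, c(1, 1, 1))
  expect_equal(s1[["volume"]], 1)
  expect_equal(s1[["surface_area"]], 6)
  cube <- array(0L, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- 1L
  sc <- shape_features(cube, c(1, 1, 1))
  expect_equal(sc[["volume"]], 1000)
  expect_equal(sc[["surface_area"]], 600)
  expect_equal(sc[["sphericity"]], pi^(1 / 3) * (6 * 1000)^(2 / 3) / 600)
  # a digital ball is more spherical than an equal-volume slab
  d <- c(20, 20, 20)
  ax <- (seq_len(20) - 10.5)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  ball <- array(as.integer(r2 <= 6^2), d)
  slab <- array(0L, d); slab[1:2, , ] <- 1L
  expect_gt(shape_features(ball, c(1, 1, 1))[["sphericity"]],
            shape_features(slab, c(1, 1, 1))[["sphericity"]])
  # non-isotropic spacing scales the volume
  expect_equal(shape_features(m1, c(1, 2, 3))[["volume"]], 6)
})

test_that("extraction partitions the tumor and repeats the bank per region", {
  v <- small_volume()
  hm <- segment_habitats(v, k_range = 2:3, seed = 9)
  ft <- extract_features(v, hm)
  expect_setequal(ft$region, c("VOIe", "VOI1", "VOI2"))
  nv <- setNames(ft$n_voxels, ft$region)
  expect_equal(nv[["VOI1"]] + nv[["VOI2"]], nv[["VOIe"]])
  feat_cols <- setdiff(names(ft), c("patient_id", "region", "n_voxels", "flagged"))
  expect_equal(length(feat_cols), 76L)
  expect_true(all(is.finite(as.matrix(ft[!ft$flagged, feat_cols]))))
  # volumes add up too (partition conservation in mm^3)
  expect_equal(ft[ft$region == "VOI1", "shape_volume"] +
                 ft[ft$region == "VOI2", "shape_volume"],
               ft[ft$region == "VOIe", "shape_volume"])
})

test_that("the optional LoG filter bank extends the feature set", {
  v <- small_volume()
  ft <- extract_features(v, NULL, preprocess_spec(filters = "log"))
  feat_cols <- setdiff(names(ft), c("patient_id", "region", "n_voxels", "flagged"))
  expect_equal(length(feat_cols), 76L + 67L)
  expect_true(any(startsWith(feat_cols, "log_")))
  expect_true(all(is.finite(as.matrix(ft[feat_cols]))))
})

test_that("intensity and texture features are translation invariant", {
  set.seed(4)
  d <- c(24, 24, 24)
  img <- array(rnorm(prod(d), 100, 15), d)
  mask <- array(0L, d); mask[4:11, 4:11, 4:11] <- 1L
  sh <- function(a, k) {
    out <- array(0, dim(a))
    out[(1 + k):dim(a)[1], , ] <- a[1:(dim(a)[1] - k), , ]
    out
  }
  img2 <- sh(img, 6); mask2 <- array(as.integer(sh(mask, 6) > 0), d)
  f1 <- extract_features(list(image = img, mask = mask, spacing = c(1, 1, 1),
                              patient_id = "a"))
  f2 <- extract_features(list(image = img2, mask = mask2, spacing = c(1, 1, 1),
                              patient_id = "a"))
  cols <- setdiff(names(f1), c("patient_id", "region", "n_voxels", "flagged"))
  expect_equal(as.numeric(f1[1, cols]), as.numeric(f2[1, cols]),
               tolerance = 1e-10)
})

test_that("tiny subregions are flagged and excluded by the widener", {
  v <- small_volume()
  hm <- segment_habitats(v, k_range = 2:3, seed = 9)
  # force a tiny VOI2 by relabelling all but 3 voxels of habitat 2 to 1
  idx <- which(hm$labels == 2)
  hm$labels[idx[-(1:3)]] <- 1L
  ft <- extract_features(v, hm)
  expect_true(ft$flagged[ft$region == "VOI2"])
  expect_true(all(is.na(ft[ft$region == "VOI2", "fo_mean"])))
  wide <- pivot_features(ft)
  expect_equal(nrow(wide), 0L)   # the only patient had a flagged region
  wide2 <- pivot_features(ft, drop_flagged = FALSE)
  expect_equal(nrow(wide2), 1L)
})

test_that("homogeneous tumors show smaller between-subregion contrast", {
  spec_two <- cohort_spec(image_shape = c(20L, 20L, 20L), radius_range = c(5, 7),
                          mean_jitter_sd = 0)
  spec_one <- cohort_spec(image_shape = c(20L, 20L, 20L), radius_range = c(5, 7),
                          intensity_means = c(120, 120), mean_jitter_sd = 0)
  gap <- function(spec, seed) {
    set.seed(seed)
    v <- generate_tumor_volume(spec, data.frame(patient_id = "P", grade = "low"))
    hm <- segment_habitats(v, k_range = 2:2, seed = seed)
    ft <- extract_features(v, hm)
    abs(ft[ft$region == "VOI1", "fo_mean"] - ft[ft$region == "VOI2", "fo_mean"])
  }
  gaps_two <- vapply(1:4, function(s) gap(spec_two, s), numeric(1))
  gaps_one <- vapply(1:4, function(s) gap(spec_one, s), numeric(1))
  expect_gt(min(gaps_two), max(gaps_one))
})

test_that("misaligned grids are rejected", {
  v <- small_volume()
  hm <- segment_habitats(v, k_range = 2:2, seed = 1)
  hm$labels <- hm$labels[1:10, 1:10, 1:10]
  expect_error(extract_features(v, hm), "misaligned")
  expect_error(extract_features(v, NULL, mask = array(1L, c(2, 2, 2))),
               "misaligned")
})
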