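# IBSI-style feature families computed on a discretized region. All texture
# functions take `lv`: a 3-D integer array with gray levels 1..n_levels inside
# the region and 0 elsewhere.

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts co-occurring level pairs at the given integer voxel offset, within
#' the region only, symmetrized (both directions accumulated).
#'
#' @param lv 3-D integer array, levels `1..n_levels` in-region, 0 outside.
#' @param n_levels number of gray levels.
#' @param offset integer triple, e.g. `c(0, 1, 0)`.
#' @return `n_levels` x `n_levels` symmetric count matrix.
#' @export
glcm_matrix <- function(lv, n_levels, offset) {
  coords <- which(lv > 0L, arr.ind = TRUE)
  d <- dim(lv)
  nb <- sweep(coords, 2, as.integer(offset), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  g1 <- lv[coords[ok, , drop = FALSE]]
  g2 <- lv[nb[ok, , drop = FALSE]]
  keep <- g2 > 0L
  g1 <- g1[keep]; g2 <- g2[keep]
  m <- matrix(tabulate((g1 - 1L) * n_levels + g2, n_levels * n_levels),
              n_levels, n_levels)
  # tabulate fills [g2, g1]; symmetrize
  m + t(m)
}

.glcm_feature_vec <- function(P) {
  G <- nrow(P)
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  dk <- abs(i - j)
  pd <- vapply(0:(G - 1), function(k) sum(p[dk == k]), numeric(1))
  sk <- i + j
  ps <- vapply(2:(2 * G), function(k) sum(p[sk == k]), numeric(1))
  da <- sum((0:(G - 1)) * pd)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  c(autocorrelation = sum(i * j * p),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1,
    difference_average = da,
    difference_entropy = ent(pd),
    difference_variance = sum(((0:(G - 1)) - da)^2 * pd),
    joint_energy = sum(p^2),
    joint_entropy = ent(p),
    idm = sum(p / (1 + (i - j)^2)),
    id = sum(p / (1 + abs(i - j))),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(p),
    sum_average = sum((2:(2 * G)) * ps),
    sum_entropy = ent(ps))
}

#' Direction-averaged GLCM features
#'
#' Symmetric co-occurrence matrices are accumulated for each of the 13 unique
#' 3-D directions at distance 1, normalized per direction, and the 18 features
#' are averaged over directions with at least one voxel pair.
#'
#' @inheritParams glcm_matrix
#' @param offsets matrix of direction offsets (rows), default [offsets13()].
#' @return named numeric vector of 18 features.
#' @export
glcm_features <- function(lv, n_levels, offsets = offsets13()) {
  if (sum(lv > 0L) < 2) stop("GLCM requires a region with at least 2 voxels")
  feats <- NULL
  for (r in seq_len(nrow(offsets))) {
    P <- glcm_matrix(lv, n_levels, offsets[r, ])
    if (sum(P) == 0) next
    feats <- rbind(feats, .glcm_feature_vec(P))
  }
  if (is.null(feats)) stop("no co-occurring voxel pairs in any direction")
  colMeans(feats)
}

#' Gray-level run-length matrix for one direction
#'
#' A run is a maximal set of consecutive voxels along the offset direction
#' sharing one gray level, entirely inside the region.
#'
#' @inheritParams glcm_matrix
#' @return count matrix, rows = gray level, columns = run length.
#' @export
glrlm_matrix <- function(lv, n_levels, offset) {
  coords <- which(lv > 0L, arr.ind = TRUE)
  n <- nrow(coords)
  offset <- as.integer(offset)
  a1 <- which(offset != 0L)[1]
  s <- coords[, a1] * offset[a1]               # step index along the ray
  key <- coords - outer(s, offset)             # constant per line
  d <- max(dim(lv))
  M <- 4L * d + 8L
  keyid <- (key[, 1] + 2 * d) + (key[, 2] + 2 * d) * M + (key[, 3] + 2 * d) * M^2
  ord <- order(keyid, s)
  g <- lv[coords][ord]; so <- s[ord]; ko <- keyid[ord]
  newrun <- c(TRUE, ko[-1] != ko[-n] | so[-1] != so[-n] + 1 | g[-1] != g[-n])
  runid <- cumsum(newrun)
  len <- tabulate(runid)
  gray <- g[newrun]
  maxlen <- max(len)
  matrix(tabulate((gray - 1L) * maxlen + len, n_levels * maxlen),
         maxlen, n_levels, byrow = FALSE) |> t()
}

.rl_feature_vec <- function(P, n_voxels, prefix_small = "sre") {
  # shared size-weighted formulas for GLRLM (j = run length) and GLSZM (j = zone size)
  i <- row(P); j <- col(P)
  Nr <- sum(P)
  p <- P / Nr
  pg <- rowSums(P); pr <- colSums(P)
  jj <- seq_len(ncol(P)); ii <- seq_len(nrow(P))
  mug <- sum(i * p); mur <- sum(j * p)
  pe <- p[p > 0]
  c(small = sum(pr / jj^2) / 1,
    large = sum(pr * jj^2) / 1,
    gln = sum(pg^2) / Nr,
    glnn = sum(pg^2) / Nr^2,
    sn = sum(pr^2) / Nr,
    snn = sum(pr^2) / Nr^2,
    pct = Nr / n_voxels,
    glv = sum((i - mug)^2 * p),
    sv = sum((j - mur)^2 * p),
    entropy = -sum(pe * log2(pe)),
    lgl = sum(pg / ii^2) / Nr,
    hgl = sum(pg * ii^2) / Nr,
    small_lgl = sum(P / (i^2 * j^2)) / Nr,
    small_hgl = sum(P * i^2 / j^2) / Nr,
    large_lgl = sum(P * j^2 / i^2) / Nr,
    large_hgl = sum(P * i^2 * j^2) / Nr)
}

#' Direction-averaged gray-level run-length features
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (SRE, LRE, GLN, GLNN, RLN,
#'   RLNN, RP, GLV, RV, run entropy, and low/high gray-level run emphases).
#' @export
glrlm_features <- function(lv, n_levels, offsets = offsets13()) {
  nvox <- sum(lv > 0L)
  if (nvox == 0) stop("empty region")
  feats <- NULL
  for (r in seq_len(nrow(offsets))) {
    P <- glrlm_matrix(lv, n_levels, offsets[r, ])
    v <- .rl_feature_vec(P, nvox)
    v["small"] <- sum(colSums(P) / seq_len(ncol(P))^2) / sum(P)
    v["large"] <- sum(colSums(P) * seq_len(ncol(P))^2) / sum(P)
    feats <- rbind(feats, v)
  }
  out <- colMeans(feats)
  names(out) <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                  "rv", "run_entropy", "lglre", "hglre", "srlgle", "srhgle",
                  "lrlgle", "lrhgle")
  out
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the region
#' (direction-free, so there is a single matrix).
#'
#' @inheritParams glcm_matrix
#' @return count matrix, rows = gray level, columns = zone size.
#' @export
glszm_matrix <- function(lv, n_levels) {
  coords <- which(lv > 0L, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) stop("empty region")
  vid <- array(0L, dim(lv))
  vid[coords] <- seq_len(n)
  d <- dim(lv)
  offs <- offsets13()
  e_from <- integer(0); e_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    v1 <- vid[coords[ok, , drop = FALSE]]
    v2 <- vid[nb[ok, , drop = FALSE]]
    same <- v2 > 0L & lv[coords[ok, , drop = FALSE]] == lv[nb[ok, , drop = FALSE]]
    e_from <- c(e_from, v1[same]); e_to <- c(e_to, v2[same])
  }
  g <- igraph::make_graph(rbind(e_from, e_to), n = n, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  lev <- lv[coords][match(seq_along(sizes), comp$membership)]
  maxsz <- max(sizes)
  t(matrix(tabulate((lev - 1L) * maxsz + sizes, n_levels * maxsz), maxsz, n_levels))
}

#' Gray-level size-zone features
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features (SAE, LAE, GLN, GLNN, SZN,
#'   SZNN, ZP, GLV, ZV, zone entropy, and low/high gray-level zone emphases).
#' @export
glszm_features <- function(lv, n_levels) {
  nvox <- sum(lv > 0L)
  if (nvox == 0) stop("empty region")
  P <- glszm_matrix(lv, n_levels)
  v <- .rl_feature_vec(P, nvox)
  v["small"] <- sum(colSums(P) / seq_len(ncol(P))^2) / sum(P)
  v["large"] <- sum(colSums(P) * seq_len(ncol(P))^2) / sum(P)
  names(v) <- c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                "zv", "zone_entropy", "lglze", "hglze", "salgle", "sahgle",
                "lalgle", "lahgle")
  v
}

#' First-order intensity statistics
#'
#' Entropy and uniformity are computed on the discretized histogram; variance,
#' skewness and kurtosis use population (denominator n) moments; kurtosis is
#' not excess-corrected. A constant region yields variance 0, entropy 0 and
#' uniformity 1.
#'
#' @param x numeric vector of masked raw intensities.
#' @param n_levels gray levels for the histogram-based features.
#' @return named numeric vector of 17 features.
#' @export
first_order_features <- function(x, n_levels = 25L) {
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  lev <- discretize_gray(x, n_levels)
  p <- tabulate(lev, n_levels) / n
  pe <- p[p > 0]
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  mid <- x[x >= q[1] & x <= q[4]]
  c(mean = m,
    median = stats::median(x),
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2),
    entropy = -sum(pe * log2(pe)),
    minimum = min(x),
    maximum = max(x),
    range = diff(range(x)),
    mad = mean(abs(x - m)),
    rms = sqrt(mean(x^2)),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2],
    robust_mad = mean(abs(mid - mean(mid))),
    uniformity = sum(p^2))
}

#' Shape features of a binary mask
#'
#' Volume is voxel count times voxel volume; surface area is obtained by
#' counting exposed voxel faces; sphericity is
#' `pi^(1/3) * (6V)^(2/3) / A`. Axis lengths are `4 * sqrt(lambda)` from the
#' eigenvalues of the physical-coordinate covariance.
#'
#' @param mask 3-D binary array.
#' @param spacing numeric triple, mm per voxel.
#' @return named numeric vector of 9 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  coords <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) stop("empty mask")
  voxvol <- prod(spacing)
  V <- n * voxvol
  d <- dim(mask)
  A <- 0
  surf <- rep(FALSE, n)
  for (axis in 1:3) {
    face <- voxvol / spacing[axis]
    for (dir in c(-1L, 1L)) {
      nb <- coords
      nb[, axis] <- nb[, axis] + dir
      outside <- nb[, axis] < 1 | nb[, axis] > d[axis]
      exposed <- outside
      inb <- !outside
      if (any(inb)) exposed[inb] <- mask[nb[inb, , drop = FALSE]] == 0
      A <- A + sum(exposed) * face
      surf <- surf | exposed
    }
  }
  ph <- sweep(coords, 2, spacing, `*`)
  maxdiam <- if (sum(surf) >= 2) max(stats::dist(ph[surf, , drop = FALSE])) else 0
  if (n > 1) {
    ev <- sort(eigen(stats::cov(ph), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    axes <- c(0, 0, 0); flat <- 1
  }
  c(volume = V,
    surface_area = A,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    surface_volume_ratio = A / V,
    max_diameter_3d = maxdiam,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    flatness = flat)
}
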