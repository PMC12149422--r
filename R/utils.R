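# Internal 3-D array helpers shared by the simulator, segmentation and
# feature-extraction code. All operate on plain numeric 3-D arrays.

# Shift an array along one dimension with edge replication.
shift3d <- function(arr, offset, dim_idx) {
  d <- dim(arr)
  idx <- seq_len(d[dim_idx]) + offset
  idx <- pmin(pmax(idx, 1L), d[dim_idx])
  switch(dim_idx,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with edge replication; sigma in voxels.
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- arr
  for (dd in 1:3) {
    acc <- array(0, dim(out))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift3d(out, j - r - 1L, dd)
    }
    out <- acc
  }
  out
}

# Local mean and standard deviation over a cubic neighborhood of given
# radius (edge-replicated). Returns a list of two arrays.
local_stats3d <- function(arr, radius = 1L) {
  offs <- (-radius):radius
  n <- length(offs)^3
  s <- array(0, dim(arr))
  s2 <- array(0, dim(arr))
  for (ox in offs) {
    ax <- shift3d(arr, ox, 1L)
    for (oy in offs) {
      axy <- shift3d(ax, oy, 2L)
      for (oz in offs) {
        v <- shift3d(axy, oz, 3L)
        s <- s + v
        s2 <- s2 + v * v
      }
    }
  }
  m <- s / n
  v <- pmax(s2 / n - m * m, 0)
  list(mean = m, sd = sqrt(v))
}

# Trilinear (method = "linear") or nearest-neighbour (method = "nearest")
# resampling of a 3-D array from `spacing` (mm/voxel) to `target` spacing.
# Voxel centres are at (i - 0.5) * spacing in each axis.
resample3d <- function(arr, spacing, target, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d_in <- dim(arr)
  d_out <- pmax(1L, as.integer(round(d_in * spacing / target)))
  coords <- lapply(1:3, function(a) {
    phys <- (seq_len(d_out[a]) - 0.5) * target[a]
    phys / spacing[a] + 0.5  # fractional input index
  })
  if (method == "nearest") {
    ix <- pmin(pmax(round(coords[[1]]), 1L), d_in[1])
    iy <- pmin(pmax(round(coords[[2]]), 1L), d_in[2])
    iz <- pmin(pmax(round(coords[[3]]), 1L), d_in[3])
    return(array(arr[as.matrix(expand.grid(x = ix, y = iy, z = iz))], d_out))
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coords[[a]]), 1L), d_in[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d_in[a]))
  fr <- lapply(1:3, function(a) pmin(pmax(coords[[a]] - lo[[a]], 0), 1))
  g <- expand.grid(x = seq_len(d_out[1]), y = seq_len(d_out[2]), z = seq_len(d_out[3]))
  out <- numeric(nrow(g))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- (if (cx == 0) lo[[1]] else hi[[1]])[g$x]
    iy <- (if (cy == 0) lo[[2]] else hi[[2]])[g$y]
    iz <- (if (cz == 0) lo[[3]] else hi[[3]])[g$z]
    wx <- if (cx == 0) 1 - fr[[1]][g$x] else fr[[1]][g$x]
    wy <- if (cy == 0) 1 - fr[[2]][g$y] else fr[[2]][g$y]
    wz <- if (cz == 0) 1 - fr[[3]][g$z] else fr[[3]][g$z]
    out <- out + wx * wy * wz * arr[cbind(ix, iy, iz)]
  }
  array(out, d_out)
}

# Deterministic fan-out of one master seed into per-stage sub-seeds.
fan_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# The 13 unique 3-D direction offsets at Chebyshev distance 1 (half of the
# 26-neighbourhood; the other half are their negatives).
offsets13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  unname(offs[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
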