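#' Voxel descriptor matrix for habitat clustering
#'
#' One row per mask voxel; columns are the raw intensity plus the local mean
#' and local standard deviation over a cubic neighborhood, which let the
#' clustering separate regions by texture as well as density.
#'
#' @param image 3-D numeric array.
#' @param mask 3-D binary array of the same shape.
#' @param radius neighborhood radius in voxels (default 1, i.e. 3x3x3).
#' @return numeric matrix with columns `intensity`, `local_mean`, `local_sd`.
#' @export
voxel_features <- function(image, mask, radius = 1L) {
  stopifnot(all(dim(image) == dim(mask)))
  if (sum(mask) == 0) stop("mask is empty")
  ls <- local_stats3d(image, radius)
  X <- cbind(intensity = image[mask == 1],
             local_mean = ls$mean[mask == 1],
             local_sd = ls$sd[mask == 1])
  if (any(!is.finite(X))) stop("non-finite voxel descriptors")
  X
}

# log-density of rows of X under N(mu, Sigma), with Cholesky; Sigma already floored.
.log_dmvnorm <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  xc <- sweep(X, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

.floor_cov <- function(sigma, floor) {
  s <- (sigma + t(sigma)) / 2
  ev <- eigen(s, symmetric = TRUE)
  ev$values <- pmax(ev$values, floor)
  ev$vectors %*% (ev$values * t(ev$vectors))
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Full-covariance GMM fitted by EM with random restarts. The log-likelihood
#' is checked to be non-decreasing at every iteration; near-singular
#' covariances are handled by eigenvalue flooring (a small fraction of the
#' pooled data variance), never by failure.
#'
#' @param X numeric matrix (observations x features).
#' @param k number of components (>= 1).
#' @param n_init number of random restarts; the best log-likelihood wins.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor_frac covariance eigenvalue floor as a fraction of the mean
#'   data variance.
#' @return list with `weights`, `means` (k x d), `covariances` (d x d x k),
#'   `responsibilities` (n x k, rows sum to 1), `loglik`, `loglik_trace`,
#'   `n_params`, `converged`.
#' @export
fit_gmm <- function(X, k, n_init = 5L, tol = 1e-6, max_iter = 200L,
                    var_floor_frac = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("fewer observations (", n, ") than components (", k, ")")
  floor_val <- var_floor_frac * mean(apply(X, 2, stats::var)) + 1e-12

  if (k == 1L) {
    mu <- colMeans(X)
    sigma <- crossprod(sweep(X, 2, mu)) / n      # ML covariance, denominator n
    sigma <- .floor_cov(sigma, floor_val)
    ll <- sum(.log_dmvnorm(X, mu, sigma))
    return(list(weights = 1, means = matrix(mu, 1), covariances = array(sigma, c(d, d, 1)),
                responsibilities = matrix(1, n, 1), loglik = ll, loglik_trace = ll,
                n_params = d + d * (d + 1) / 2, converged = TRUE))
  }

  pooled <- .floor_cov(crossprod(sweep(X, 2, colMeans(X))) / n, floor_val)
  best <- NULL
  for (init in seq_len(n_init)) {
    # random restart: k-means from randomly sampled centres, then EM
    km <- tryCatch(suppressWarnings(
      stats::kmeans(X, centers = X[sample.int(n, k), , drop = FALSE], iter.max = 20L)),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) {
      mu <- matrix(km$centers, k, d)
      sigma <- array(0, c(d, d, k))
      for (j in seq_len(k)) {
        sel <- km$cluster == j
        sigma[, , j] <- if (sum(sel) > d)
          .floor_cov(crossprod(sweep(X[sel, , drop = FALSE], 2, mu[j, ])) / sum(sel), floor_val)
        else pooled
      }
      w <- pmax(km$size, 1) / sum(pmax(km$size, 1))
    } else {
      mu <- X[sample.int(n, k), , drop = FALSE]
      sigma <- array(0, c(d, d, k))
      for (j in seq_len(k)) sigma[, , j] <- pooled
      w <- rep(1 / k, k)
    }
    fit <- .em_run(X, k, w, mu, sigma, tol, max_iter, floor_val)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# EM main loop; 1-D data take a scalar fast path (no Cholesky in the hot loop).
.em_run <- function(X, k, w, mu, sigma, tol, max_iter, floor_val) {
  n <- nrow(X); d <- ncol(X)
  one_d <- d == 1L
  x <- if (one_d) X[, 1] else NULL
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  logd <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    if (one_d) {
      for (j in seq_len(k))
        logd[, j] <- log(w[j]) +
          stats::dnorm(x, mu[j, 1], sqrt(sigma[1, 1, j]), log = TRUE)
    } else {
      for (j in seq_len(k))
        logd[, j] <- log(w[j]) + .log_dmvnorm(X, mu[j, ], sigma[, , j])
    }
    m <- logd[, 1]
    if (k > 1) for (j in 2:k) m <- pmax(m, logd[, j])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (it > 1 && ll < ll_prev - 1e-6 * (abs(ll_prev) + 1))
      stop("EM log-likelihood decreased; numerical failure")
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    if (it > 1 && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / n
    if (one_d) {
      mu[, 1] <- colSums(resp * x) / nk
      for (j in seq_len(k))
        sigma[1, 1, j] <- max(sum(resp[, j] * (x - mu[j, 1])^2) / nk[j], floor_val)
    } else {
      for (j in seq_len(k)) {
        mu[j, ] <- colSums(resp[, j] * X) / nk[j]
        xc <- sweep(X, 2, mu[j, ])
        sigma[, , j] <- .floor_cov(crossprod(xc * resp[, j], xc) / nk[j], floor_val)
      }
    }
  }
  list(weights = w, means = mu, covariances = sigma,
       responsibilities = resp, loglik = ll, loglik_trace = trace,
       n_params = (k - 1) + k * d + k * d * (d + 1) / 2,
       converged = converged)
}

#' Bayesian information criterion
#'
#' `BIC = n_params * ln(n_obs) - 2 * loglik`; lower is better, so the model
#' count is chosen as the arg-min over candidate K.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_obs number of observations (>= 1).
#' @return the BIC value.
#' @export
gmm_bic <- function(loglik, n_params, n_obs) {
  if (n_obs < 1) stop("n_obs must be >= 1")
  n_params * log(n_obs) - 2 * loglik
}

#' Segment a tumor into habitats by GMM with BIC model selection
#'
#' Fits a per-patient Gaussian mixture on the voxel descriptors of the mask
#' for every candidate K, selects the K with minimal BIC (ties broken toward
#' smaller K), assigns each voxel to its maximum-responsibility component, and
#' relabels clusters in ascending order of mean intensity so that label 1 is
#' always the lowest-density subregion.
#'
#' By default the mixture is fitted on voxel intensity alone. The local mean
#' and local sd descriptors of [voxel_features()] can be added via
#' `descriptors`, but note that neighborhood statistics straddle habitat
#' boundaries and so introduce a genuine third (bridge) population in feature
#' space, which BIC will count; intensity-only clustering matches the
#' per-voxel mixture semantics of a density habitat.
#'
#' @param vol a `tumor_volume` (or any list with `image` and `mask`).
#' @param k_range candidate cluster counts, default `2:10`.
#' @param seed integer seed controlling restarts.
#' @param descriptors subset of `c("intensity", "local_mean", "local_sd")`.
#' @param radius neighborhood radius for [voxel_features()].
#' @param ... passed on to [fit_gmm()].
#' @return object of class `habitat_map`: list with `labels` (3-D integer
#'   array, 0 outside the mask), `k_selected`, `bic_by_k` (named numeric),
#'   `cluster_order_stat` (per-cluster mean intensity, strictly increasing),
#'   and `mask`.
#' @export
segment_habitats <- function(vol, k_range = 2:10, seed = 1L,
                             descriptors = "intensity", radius = 1L, ...) {
  if (sum(vol$mask) == 0) stop("mask is empty")
  descriptors <- match.arg(descriptors,
                           c("intensity", "local_mean", "local_sd"),
                           several.ok = TRUE)
  X <- voxel_features(vol$image, vol$mask, radius)[, descriptors, drop = FALSE]
  set.seed(as.integer(seed))
  fits <- list()
  bic_by_k <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- tryCatch(fit_gmm(X, k, ...), error = function(e) {
      warning("GMM fit failed for K=", k, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    fits[[as.character(k)]] <- fit
    bic_by_k[i] <- gmm_bic(fit$loglik, fit$n_params, nrow(X))
  }
  if (all(is.na(bic_by_k))) stop("GMM fitting failed for every candidate K")
  k_selected <- k_range[which.min(bic_by_k)]   # first minimum -> smaller K on ties
  fit <- fits[[as.character(k_selected)]]
  comp <- max.col(fit$responsibilities, ties.method = "first")
  # relabel by ascending mean raw intensity: label 1 = low-density habitat
  intens <- vol$image[vol$mask == 1]
  means <- vapply(seq_len(k_selected),
                  function(j) mean(intens[comp == j]), numeric(1))
  ord <- order(means)
  relab <- integer(k_selected)
  relab[ord] <- seq_len(k_selected)
  labels <- array(0L, dim(vol$mask))
  labels[vol$mask == 1] <- relab[comp]
  structure(list(labels = labels, k_selected = k_selected,
                 bic_by_k = bic_by_k[!is.na(bic_by_k)],
                 cluster_order_stat = sort(means),
                 mask = vol$mask, gmm = fit),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("Habitat map: K =", x$k_selected, "selected by BIC over K in {",
      paste(names(x$bic_by_k), collapse = ", "), "}\n")
  sizes <- table(x$labels[x$labels > 0])
  cat("  subregion sizes:", paste(sizes, collapse = ", "),
      "| mean intensities:", paste(round(x$cluster_order_stat, 1), collapse = ", "), "\n")
  invisible(x)
}
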