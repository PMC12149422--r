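# Independent brute-force oracles. Everything here is written from the
# definitions (pair/run/zone enumeration, explicit ANOVA sums of squares,
# hypergeometric tails, O-E-V tables) and never calls the package's own
# implementation paths.

# ---- GLCM: enumerate all voxel pairs directly -------------------------------
oracle_glcm <- function(lv, n_levels, offset) {
  d <- dim(lv)
  P <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    g1 <- lv[x, y, z]
    if (g1 == 0) next
    q <- c(x, y, z) + offset
    if (any(q < 1) || any(q > d)) next
    g2 <- lv[q[1], q[2], q[3]]
    if (g2 == 0) next
    P[g1, g2] <- P[g1, g2] + 1
    P[g2, g1] <- P[g2, g1] + 1
  }
  P
}

oracle_glcm_features <- function(P) {
  G <- nrow(P); p <- P / sum(P)
  f <- c(autocorrelation = 0, joint_average = 0, cluster_prominence = 0,
         cluster_shade = 0, cluster_tendency = 0, contrast = 0,
         correlation = 0, difference_average = 0, difference_entropy = 0,
         difference_variance = 0, joint_energy = 0, joint_entropy = 0,
         idm = 0, id = 0, inverse_variance = 0, maximum_probability = 0,
         sum_average = 0, sum_entropy = 0)
  mu <- 0
  for (i in 1:G) for (j in 1:G) mu <- mu + i * p[i, j]
  sig2 <- 0
  for (i in 1:G) for (j in 1:G) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  pd <- rep(0, G); ps <- rep(0, 2 * G)
  for (i in 1:G) for (j in 1:G) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j] <- ps[i + j] + p[i, j]
  }
  da <- sum((0:(G - 1)) * pd)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * v
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - 2 * mu)^4 * v
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - 2 * mu)^3 * v
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - 2 * mu)^2 * v
    f["contrast"] <- f["contrast"] + (i - j)^2 * v
    f["joint_energy"] <- f["joint_energy"] + v^2
    if (v > 0) f["joint_entropy"] <- f["joint_entropy"] - v * log2(v)
    f["idm"] <- f["idm"] + v / (1 + (i - j)^2)
    f["id"] <- f["id"] + v / (1 + abs(i - j))
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + v / (i - j)^2
  }
  f["joint_average"] <- mu
  f["correlation"] <- if (sig2 > 0) (f[["autocorrelation"]] - mu^2) / sig2 else 1
  f["difference_average"] <- da
  f["difference_entropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  f["difference_variance"] <- sum(((0:(G - 1)) - da)^2 * pd)
  f["maximum_probability"] <- max(p)
  f["sum_average"] <- sum((1:(2 * G)) * ps)
  f["sum_entropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  f
}

# ---- GLRLM: walk every ray voxel by voxel -----------------------------------
oracle_glrlm <- function(lv, n_levels, offset) {
  d <- dim(lv)
  inb <- function(q) all(q >= 1) && all(q <= d)
  runs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    g <- lv[x, y, z]
    if (g == 0) next
    prev <- c(x, y, z) - offset
    if (inb(prev) && lv[prev[1], prev[2], prev[3]] == g) next  # not a run start
    len <- 1
    q <- c(x, y, z) + offset
    while (inb(q) && lv[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + offset
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  runs <- do.call(rbind, runs)
  P <- matrix(0, n_levels, max(runs[, 2]))
  for (r in seq_len(nrow(runs))) P[runs[r, 1], runs[r, 2]] <- P[runs[r, 1], runs[r, 2]] + 1
  P
}

# ---- GLSZM: zones by breadth-first search over the 26-neighbourhood ---------
oracle_glszm <- function(lv, n_levels) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0 || seen[x, y, z]) next
    g <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- v + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lv[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zones <- do.call(rbind, zones)
  P <- matrix(0, n_levels, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  P
}

# size-weighted features from a gray-level x size count matrix, typed from the
# standard formulas (used for both GLRLM and GLSZM oracles)
oracle_size_features <- function(P, n_voxels) {
  Nr <- sum(P)
  p <- P / Nr
  G <- nrow(P); L <- ncol(P)
  pg <- rowSums(P); pr <- colSums(P)
  small <- 0; large <- 0; lgl <- 0; hgl <- 0
  s_lgl <- 0; s_hgl <- 0; l_lgl <- 0; l_hgl <- 0
  mug <- 0; mur <- 0; ent <- 0
  for (i in 1:G) for (j in 1:L) {
    v <- P[i, j]
    s_lgl <- s_lgl + v / (i^2 * j^2)
    s_hgl <- s_hgl + v * i^2 / j^2
    l_lgl <- l_lgl + v * j^2 / i^2
    l_hgl <- l_hgl + v * i^2 * j^2
    mug <- mug + i * p[i, j]; mur <- mur + j * p[i, j]
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  }
  glv <- 0; sv <- 0
  for (i in 1:G) for (j in 1:L) {
    glv <- glv + (i - mug)^2 * p[i, j]
    sv <- sv + (j - mur)^2 * p[i, j]
  }
  c(small = sum(pr / (1:L)^2) / Nr,
    large = sum(pr * (1:L)^2) / Nr,
    gln = sum(pg^2) / Nr,
    glnn = sum(pg^2) / Nr^2,
    sn = sum(pr^2) / Nr,
    snn = sum(pr^2) / Nr^2,
    pct = Nr / n_voxels,
    glv = glv,
    sv = sv,
    entropy = ent,
    lgl = sum(pg / (1:G)^2) / Nr,
    hgl = sum(pg * (1:G)^2) / Nr,
    small_lgl = s_lgl / Nr,
    small_hgl = s_hgl / Nr,
    large_lgl = l_lgl / Nr,
    large_hgl = l_hgl / Nr)
}

# ---- ICC(2,1) from explicit sums of squares ---------------------------------
oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# ---- AUC by Mann-Whitney pair counting --------------------------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# ---- Youden by exhaustive threshold scan ------------------------------------
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- -Inf; best_cut <- NA
  for (ct in cand) {
    pred <- as.integer(scores >= ct)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best + 1e-12) { best <- j; best_cut <- ct }
  }
  list(cutoff = best_cut, j = best)
}

# ---- log-rank by explicit O-E-V table ---------------------------------------
oracle_logrank <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  grp <- c(rep(1, length(timeA)), rep(2, length(timeB)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# ---- Fisher exact two-sided p by hypergeometric enumeration -----------------
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- hypergeometric upper-tail by direct summation --------------------------
oracle_hyper_tail <- function(overlap, term_size, module_size, universe_size) {
  ks <- overlap:min(term_size, module_size)
  sum(stats::dhyper(ks, term_size, universe_size - term_size, module_size))
}

# ---- TOM by triple-sum enumeration ------------------------------------------
oracle_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  TOM <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# ---- LASSO KKT residual (gaussian objective 1/(2n)||y-Xb||^2 + lambda||b||_1)
oracle_kkt_residual <- function(X, y, intercept, beta, lambda) {
  n <- nrow(X)
  r <- y - intercept - as.numeric(X %*% beta)
  g <- as.numeric(crossprod(X, r)) / n
  res <- numeric(length(beta))
  active <- abs(beta) > 0
  res[active] <- abs(g[active] - lambda * sign(beta[active]))
  res[!active] <- pmax(abs(g[!active]) - lambda, 0)
  max(c(res, abs(mean(r))))   # intercept stationarity included
}

# ---- adjusted Rand index from the pair-counting definition ------------------
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  ntot <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / ntot
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# random discretized 6x6x6 region with a hole, for texture-oracle tests
random_region <- function(n_levels = 4, shape = c(6, 6, 6), p_in = 0.7) {
  lv <- array(0L, shape)
  inside <- stats::runif(prod(shape)) < p_in
  lv[inside] <- sample.int(n_levels, sum(inside), replace = TRUE)
  lv
}
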