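#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with mean
#' squares from the two-way subject x rater ANOVA (n subjects, k raters).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; no
#'   missing cells.
#' @return ICC value in `[-1, 1]`. Zero between-subject variance yields a
#'   value <= 0 with a warning, never an error.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("missing or non-finite cells")
  if (stats::var(as.vector(ratings)) < 1e-12 * (mean(ratings)^2 + 1)) {
    warning("degenerate ratings (no variance); ICC undefined, returning 0")
    return(0)
  }
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) {
    warning("degenerate ratings (no variance); ICC undefined, returning 0")
    return(0)
  }
  val <- (msr - mse) / denom
  if (msr <= mse)
    warning("between-subject variance does not exceed error; ICC <= 0")
  val
}

#' Filter features by intra- and inter-observer reproducibility
#'
#' Computes, for every feature column, the ICC(2,1) between the primary
#' delineation and (a) the same observer's repeat (`icc_intra`) and (b) the
#' second observer's delineation (`icc_inter`), on the common patient subset.
#' A feature is retained only when **both** ICCs strictly exceed the
#' threshold.
#'
#' @param primary,intra,inter wide feature tables (one row per patient, a
#'   `patient_id` column plus feature columns) from the primary mask, the
#'   intra-observer repeat mask and the inter-observer mask.
#' @param threshold retention threshold on both ICCs (default 0.75, strict
#'   inequality).
#' @return list with `retained` (character vector of feature names) and
#'   `report` (data.frame: feature, icc_intra, icc_inter, retained).
#' @export
filter_features_icc <- function(primary, intra, inter, threshold = 0.75) {
  common <- Reduce(intersect, list(primary$patient_id, intra$patient_id,
                                   inter$patient_id))
  if (length(common) < 2) stop("fewer than 2 common patients across tables")
  feats <- Reduce(intersect, list(names(primary), names(intra), names(inter)))
  feats <- setdiff(feats, "patient_id")
  a <- primary[match(common, primary$patient_id), , drop = FALSE]
  b <- intra[match(common, intra$patient_id), , drop = FALSE]
  c_ <- inter[match(common, inter$patient_id), , drop = FALSE]
  rows <- lapply(feats, function(f) {
    x <- a[[f]]; yi <- b[[f]]; ye <- c_[[f]]
    ok <- is.finite(x) & is.finite(yi) & is.finite(ye)
    if (sum(ok) < 2)
      return(data.frame(feature = f, icc_intra = NA_real_,
                        icc_inter = NA_real_, retained = FALSE))
    i1 <- suppressWarnings(icc(cbind(x[ok], yi[ok])))
    i2 <- suppressWarnings(icc(cbind(x[ok], ye[ok])))
    data.frame(feature = f, icc_intra = i1, icc_inter = i2,
               retained = isTRUE(i1 > threshold && i2 > threshold))
  })
  report <- do.call(rbind, rows)
  list(retained = report$feature[report$retained], report = report)
}
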