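#' Min-max normalization with training-set bounds
#'
#' Scales each feature linearly to `[0, 1]` using the training table's min and
#' max; the same bounds are applied unchanged to any further tables, so test
#' values outside the training range may fall outside `[0, 1]` (no clamping).
#' Constant training columns map to 0 with a warning.
#'
#' @param train data.frame/matrix of training features (numeric columns).
#' @param ... further tables to scale with the training bounds.
#' @return list with `train`, scaled further tables (same order, named as
#'   passed), and `bounds` (data.frame feature/min/max).
#' @export
normalize_minmax <- function(train, ...) {
  others <- list(...)
  num_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  lo <- vapply(train[num_cols], min, numeric(1))
  hi <- vapply(train[num_cols], max, numeric(1))
  const <- hi == lo
  if (any(const))
    warning("constant training column(s) mapped to 0: ",
            paste(num_cols[const], collapse = ", "))
  scale_tab <- function(tab) {
    for (j in num_cols) {
      tab[[j]] <- if (const[[j]]) 0 else (tab[[j]] - lo[[j]]) / (hi[[j]] - lo[[j]])
    }
    tab
  }
  out <- c(list(train = scale_tab(train)), lapply(others, scale_tab))
  out$bounds <- data.frame(feature = num_cols, min = unname(lo), max = unname(hi))
  out
}

#' Spearman redundancy filter
#'
#' Among any feature pair with absolute Spearman correlation above the
#' threshold, the member with the larger mean absolute correlation to all
#' other features is dropped. Features are processed in name order, making the
#' result deterministic and independent of row/column order.
#'
#' @param x data.frame/matrix of numeric features.
#' @param r_threshold absolute-correlation threshold (default 0.9, strict).
#' @return character vector of retained feature names.
#' @export
spearman_redundancy_filter <- function(x, r_threshold = 0.9) {
  x <- as.data.frame(x)
  num_cols <- sort(names(x)[vapply(x, is.numeric, logical(1))])
  if (length(num_cols) < 2) return(num_cols)
  cm <- suppressWarnings(stats::cor(x[num_cols], method = "spearman"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  keep <- rep(TRUE, length(num_cols))
  names(keep) <- num_cols
  mean_abs <- rowMeans(abs(cm))
  for (a in num_cols) {
    if (!keep[a]) next
    partners <- num_cols[keep & abs(cm[a, num_cols]) > r_threshold]
    for (b in partners) {
      if (!keep[a] || !keep[b]) next
      drop <- if (mean_abs[a] >= mean_abs[b]) a else b
      keep[drop] <- FALSE
    }
  }
  num_cols[keep]
}

#' LASSO with stratified 5-fold cross-validation
#'
#' L1-penalized regression of the binary label over a log-spaced lambda path;
#' the optimal lambda minimizes the mean cross-validated loss and the final
#' model is refit on the full training data at that lambda. The default
#' family is `"gaussian"` (squared-error loss on the 0/1 label); `"binomial"`
#' gives logistic LASSO.
#'
#' @param x numeric matrix of (already scaled) features.
#' @param y binary labels (0/1 or two-level factor).
#' @param nfolds folds for cross-validation (default 5, stratified by class).
#' @param family `"gaussian"` or `"binomial"`.
#' @param seed integer seed for the fold assignment.
#' @return list with `coefficients` (named, nonzero only), `intercept`,
#'   `lambda`, `selected` (feature names), and the underlying `cv.glmnet` fit.
#' @export
lasso_cv <- function(x, y, nfolds = 5L, family = c("gaussian", "binomial"),
                     seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y01 <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  if (length(unique(y01)) < 2) stop("y must contain both classes")
  set.seed(as.integer(seed))
  foldid <- integer(length(y01))
  for (cl in unique(y01)) {           # stratified folds
    idx <- which(y01 == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  if (any(vapply(seq_len(nfolds), function(f)
    length(unique(y01[foldid == f])) < 2, logical(1))))
    stop("a fold lost one of the classes; need more samples per class")
  cv <- glmnet::cv.glmnet(x, y01, family = family, foldid = foldid,
                          standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- co[-1, 1]
  sel <- names(beta)[beta != 0]
  list(coefficients = beta[beta != 0], intercept = co[1, 1],
       lambda = cv$lambda.min, selected = sel, cv_fit = cv)
}

#' Youden-index optimal cutoff
#'
#' Scans the midpoints of adjacent sorted unique scores (plus one candidate
#' below the minimum and one above the maximum) and returns the cutoff
#' maximizing `J = sensitivity + specificity - 1` under the rule
#' high-risk iff `score >= cutoff`. Ties are broken toward the lower cutoff.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive/high grade).
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best <- list(cutoff = cand[1], youden = -Inf)
  for (ct in cand) {
    pred <- scores >= ct
    sens <- sum(pred & labels == 1) / npos
    spec <- sum(!pred & labels == 0) / nneg
    j <- sens + spec - 1
    if (j > best$youden + 1e-12) {     # strict improvement: ties keep lower cutoff
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec, youden = j)
    }
  }
  best
}

#' Build a radiomics-score model on training data
#'
#' Chains the training-only selection pipeline: min-max normalization,
#' Spearman redundancy filter, LASSO with stratified cross-validation, linear
#' radscore, and the Youden cutoff on the training scores. The returned object
#' applies the frozen bounds/coefficients/cutoff to new data without any
#' refitting.
#'
#' @param train wide feature data.frame (numeric feature columns).
#' @param y binary grade labels for the training rows (1/"high" = positive).
#' @param r_threshold Spearman redundancy threshold.
#' @param nfolds,family,seed passed to [lasso_cv()].
#' @return object of class `radscore_model`.
#' @export
build_radscore_model <- function(train, y, r_threshold = 0.9, nfolds = 5L,
                                 family = "gaussian", seed = 1L) {
  y01 <- if (is.character(y) || is.factor(y))
    as.integer(as.character(y) == "high") else as.integer(y)
  feats <- names(train)[vapply(train, is.numeric, logical(1))]
  nm <- normalize_minmax(train[feats])
  kept <- spearman_redundancy_filter(nm$train, r_threshold)
  fit <- lasso_cv(as.matrix(nm$train[kept]), y01, nfolds = nfolds,
                  family = family, seed = seed)
  scores <- fit$intercept +
    as.numeric(as.matrix(nm$train[names(fit$coefficients)]) %*% fit$coefficients)
  yj <- youden_cutoff(scores, y01)
  structure(list(selected_features = names(fit$coefficients),
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 lambda = fit$lambda,
                 bounds = nm$bounds,
                 redundancy_kept = kept,
                 cutoff = yj$cutoff,
                 youden = yj[c("sensitivity", "specificity", "youden")],
                 family = family),
            class = "radscore_model")
}

#' Compute radscores from a fitted model
#'
#' `intercept + sum(coefficient_i * x_i)` on min-max-scaled features using the
#' training bounds frozen in the model.
#'
#' @param object a `radscore_model`.
#' @param newdata data.frame containing the selected feature columns (raw,
#'   unscaled).
#' @param type `"score"` for the numeric radscore, `"risk"` for the
#'   dichotomized group (`"high"` iff score >= cutoff).
#' @param ... unused.
#' @return numeric scores or character risk groups.
#' @export
predict.radscore_model <- function(object, newdata, type = c("score", "risk"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$selected_features, names(newdata))
  if (length(missing))
    stop("missing feature(s) in newdata: ", paste(missing, collapse = ", "))
  b <- object$bounds[match(object$selected_features, object$bounds$feature), ]
  x <- as.matrix(newdata[object$selected_features])
  rng <- b$max - b$min
  rng[rng == 0] <- 1
  xs <- sweep(sweep(x, 2, b$min), 2, rng, `/`)
  xs[, b$max == b$min] <- 0
  s <- object$intercept + as.numeric(xs %*% object$coefficients)
  if (type == "score") s else ifelse(s >= object$cutoff, "high", "low")
}

#' @export
coef.radscore_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.radscore_model <- function(x, ...) {
  cat("Radscore model:", length(x$selected_features),
      "features selected by LASSO (lambda =", signif(x$lambda, 3), ")\n")
  for (f in x$selected_features)
    cat(sprintf("  %-40s %+ .4f\n", f, x$coefficients[[f]]))
  cat("  intercept", sprintf("%+.4f", x$intercept),
      "| Youden cutoff", signif(x$cutoff, 4),
      sprintf("(sens %.2f, spec %.2f)\n",
              x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}
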