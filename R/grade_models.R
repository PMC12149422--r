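#' Stratified 7:3 train/test split
#'
#' Splits patients into training and internal-test sets preserving the grade
#' proportions within one patient per stratum. The overall test size is
#' `ceiling((1 - ratio) * n)` (so 186 patients split 130/56 at ratio 0.7),
#' allocated to strata by largest remainder.
#'
#' @param labels per-patient stratification labels (e.g. grade).
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(labels, ratio = 0.7, seed = 1L) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 patients")
  tab <- table(labels)
  if (any(tab < 2)) stop("every stratum needs at least 2 patients")
  n_test <- ceiling((1 - ratio) * n - 1e-9)   # guard float fuzz (0.3*10 -> 3)
  raw <- (1 - ratio) * as.numeric(tab)
  base <- floor(raw)
  rem <- n_test - sum(base)
  ord <- order(raw - base, decreasing = TRUE)
  add <- integer(length(tab))
  if (rem > 0) add[ord[seq_len(rem)]] <- 1L
  per_stratum <- stats::setNames(base + add, names(tab))
  set.seed(as.integer(seed))
  test <- integer(0)
  for (s in names(tab)) {
    idx <- which(labels == s)
    test <- c(test, sample(idx, per_stratum[[s]]))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Train the four grade classifiers
#'
#' Random forest (500 trees), logistic regression (maximum-likelihood
#' [stats::glm()]), decision tree (rpart, gini) and an RBF-kernel SVM
#' (cost 1, decision values used as scores). All randomness is seeded.
#'
#' @param x data.frame of numeric features (training rows).
#' @param y binary labels; `"high"`/1 is the positive class.
#' @param models subset of `c("RF", "LR", "DT", "SVM")`.
#' @param seed integer seed.
#' @return named list of fitted model objects (class `grade_classifiers`).
#' @export
train_classifiers <- function(x, y, models = c("RF", "LR", "DT", "SVM"),
                              seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  y01 <- if (is.character(y) || is.factor(y))
    as.integer(as.character(y) == "high") else as.integer(y)
  if (min(table(y01)) < 2) stop("need at least 2 samples per class")
  yf <- factor(y01, levels = c(0, 1))
  const <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    warning("constant feature column(s): ", paste(names(x)[const], collapse = ", "))
  df <- cbind(x, .y = yf)
  out <- list()
  set.seed(as.integer(seed))
  if ("RF" %in% models)
    out$RF <- randomForest::randomForest(.y ~ ., data = df, ntree = 500)
  if ("LR" %in% models)
    out$LR <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  if ("DT" %in% models)
    out$DT <- rpart::rpart(.y ~ ., data = df, method = "class")
  if ("SVM" %in% models)
    out$SVM <- e1071::svm(.y ~ ., data = df, kernel = "radial", cost = 1,
                          scale = FALSE)
  class(out) <- "grade_classifiers"
  out
}

# continuous score for the positive class from any of the four models
classifier_scores <- function(model, x) {
  if (inherits(model, "randomForest"))
    return(stats::predict(model, x, type = "prob")[, "1"])
  if (inherits(model, "glm"))
    return(as.numeric(stats::predict(model, x, type = "response")))
  if (inherits(model, "rpart"))
    return(stats::predict(model, x, type = "prob")[, "1"])
  if (inherits(model, "svm")) {
    dv <- attr(stats::predict(model, x, decision.values = TRUE), "decision.values")
    s <- dv[, 1]
    if (grepl("^0/1$", colnames(dv)[1])) s <- -s  # orient toward class "1"
    return(as.numeric(s))
  }
  stop("unsupported model class")
}

classifier_labels <- function(model, x) {
  if (inherits(model, "rpart"))
    return(as.integer(as.character(stats::predict(model, x, type = "class"))))
  if (inherits(model, "glm"))
    return(as.integer(stats::predict(model, x, type = "response") >= 0.5))
  as.integer(as.character(stats::predict(model, x)))
}

#' ROC curve and AUC from continuous scores
#'
#' Trapezoidal AUC over all score thresholds (higher score = positive class).
#'
#' @param scores continuous classifier scores.
#' @param labels binary labels (1 = positive).
#' @return list with `auc` and `roc` (data.frame fpr/tpr/threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC undefined: labels contain a single class")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       roc = data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                        threshold = r$thresholds))
}

#' Evaluate a classifier on a labelled split
#'
#' Computes accuracy, and precision/recall/F1 for the positive (high-grade)
#' class, plus ROC/AUC from the model's continuous scores (trapezoidal
#' integration over all thresholds). With `average = "weighted"` the
#' per-class precision/recall/F1 are weighted by class support.
#'
#' @param model one fitted model from [train_classifiers()].
#' @param x features of the evaluation split.
#' @param y true binary labels.
#' @param average `"positive"` (default) or `"weighted"`.
#' @return object of class `evaluation_report`: list with `metrics` (named
#'   numeric: accuracy, precision, recall, f1, auc) and `roc` (data.frame
#'   fpr/tpr/threshold).
#' @export
evaluate_classifier <- function(model, x, y, average = c("positive", "weighted")) {
  average <- match.arg(average)
  y01 <- if (is.character(y) || is.factor(y))
    as.integer(as.character(y) == "high") else as.integer(y)
  pred <- classifier_labels(model, x)
  acc <- mean(pred == y01)
  prf <- function(pos) {
    tp <- sum(pred == pos & y01 == pos)
    prec <- if (sum(pred == pos) > 0) tp / sum(pred == pos) else 0
    rec <- if (sum(y01 == pos) > 0) tp / sum(y01 == pos) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  m <- if (average == "positive") prf(1) else {
    w <- c(mean(y01 == 0), mean(y01 == 1))
    w[1] * prf(0) + w[2] * prf(1)
  }
  scores <- classifier_scores(model, x)
  ra <- roc_auc(scores, y01)
  structure(list(metrics = c(accuracy = acc, precision = m[1], recall = m[2],
                             f1 = m[3], auc = ra$auc),
                 roc = ra$roc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation:",
      paste(sprintf("%s %.3f", names(x$metrics), x$metrics), collapse = ", "), "\n")
  invisible(x)
}

#' Train and evaluate all four classifiers per region
#'
#' Convenience wrapper producing the model x split metric table (the layout of
#' a prediction-performance table): one row per model and split.
#'
#' @param x_train,y_train training features/labels.
#' @param splits named list of evaluation splits, each `list(x = , y = )`.
#' @param models classifier subset.
#' @param seed integer seed.
#' @return data.frame with columns model, split, accuracy, precision, recall,
#'   f1, auc.
#' @export
evaluate_models <- function(x_train, y_train, splits,
                            models = c("RF", "LR", "DT", "SVM"), seed = 1L) {
  fits <- train_classifiers(x_train, y_train, models = models, seed = seed)
  rows <- list()
  for (mn in names(fits)) {
    for (sn in names(splits)) {
      ev <- evaluate_classifier(fits[[mn]], splits[[sn]]$x, splits[[sn]]$y)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(model = mn, split = sn, stringsAsFactors = FALSE),
              as.data.frame(as.list(ev$metrics)))
    }
  }
  do.call(rbind, rows)
}
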