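#' Kaplan-Meier survival curve
#'
#' Product-limit estimator, optionally per group. A thin wrapper around
#' [survival::survfit()] returning a plain step-function table.
#'
#' @param time event/censoring times (> 0).
#' @param event 1 = event (death), 0 = censored.
#' @param group optional group labels.
#' @return data.frame with columns `group` (if given), `time`, `surv`
#'   (non-increasing, S(0) = 1 implicit) and `n_risk`.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    return(data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  g <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  data.frame(group = g, time = fit$time, surv = fit$surv, n_risk = fit$n.risk)
}

#' Log-rank test between two groups
#'
#' Chi-square statistic (1 df) accumulated over distinct event times with the
#' hypergeometric variance, via [survival::survdiff()].
#'
#' @param time,event survival outcome.
#' @param group two-level group labels.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (sum(event) < 1) stop("log-rank test requires at least one event")
  if (length(unique(group)) != 2) stop("exactly two groups required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = p)
}

#' Two-group comparison of a clinical variable
#'
#' Categorical variables: chi-square test (without continuity correction), or
#' Fisher's exact test when any expected cell count is below 5. Continuous
#' variables: Student's t test when both groups pass a Shapiro normality check
#' at alpha 0.05, otherwise the Mann-Whitney U test (normal approximation,
#' midranks).
#'
#' @param values the variable (numeric = continuous, otherwise categorical).
#' @param group two-level grouping.
#' @param type `"auto"` (by variable class), `"categorical"` or `"continuous"`.
#' @return list with `test` (name), `statistic`, `p`.
#' @export
compare_groups <- function(values, group, type = c("auto", "categorical", "continuous")) {
  type <- match.arg(type)
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0)) stop("need two non-empty groups")
  if (type == "auto")
    type <- if (is.numeric(values)) "continuous" else "categorical"
  if (type == "categorical") {
    tab <- table(values, g)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ft <- stats::fisher.test(tab)
      return(list(test = "fisher", statistic = NA_real_, p = ft$p.value))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(test = "chisq", statistic = unname(ct$statistic), p = ct$p.value))
  }
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  normal <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }
  if (normal(a) && normal(b)) {
    tt <- stats::t.test(a, b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    list(test = "mann-whitney", statistic = unname(wt$statistic), p = wt$p.value)
  }
}

#' Compare overall survival between radscore risk groups
#'
#' Applies the training-derived Youden cutoff to the scores of one split,
#' forms high/low-risk groups and runs the log-rank test; also returns the
#' per-group Kaplan-Meier curves.
#'
#' @param scores radscores of the split.
#' @param cutoff training-derived cutoff (high risk iff score >= cutoff).
#' @param time,event survival outcome of the split.
#' @return list with `groups`, `km` (curve table) and `logrank`.
#' @export
risk_group_survival <- function(scores, cutoff, time, event) {
  grp <- ifelse(scores >= cutoff, "high_risk", "low_risk")
  if (length(unique(grp)) < 2)
    return(list(groups = grp, km = km_curve(time, event),
                logrank = list(chisq = NA_real_, p = NA_real_)))
  list(groups = grp,
       km = km_curve(time, event, grp),
       logrank = logrank_test(time, event, grp))
}
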