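check_binary_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort_ims("scores and labels differ in length", "imsvoc_input_error")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    abort_ims("both classes must be present", "imsvoc_input_error")
  }
  labels
}

#' Empirical AUC (Mann-Whitney pair statistic)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counting one half: (concordant pairs + ties/2) /
#' (n_pos * n_neg). Computed from midranks, which is algebraically the
#' same quantity.
#'
#' @param scores numeric prediction scores (higher = more class 1).
#' @param labels binary 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(3, 1, 2, 0), c(1, 1, 0, 0)) # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_scores(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' One point per distinct cutoff, from `+Inf` (nothing called positive,
#' point (0,0)) down through every observed score; the prediction rule at
#' cutoff c is `score >= c`. The trapezoidal area under the returned curve
#' equals [auc()] exactly, ties included.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return an `ims_roc` data frame with columns `cutoff`, `fpr`, `tpr`,
#'   ordered from cutoff `+Inf` downwards; starts at (0,0), ends at (1,1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_scores(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) sum(scores >= ct & labels == 1L),
                numeric(1)) / n_pos
  fpr <- vapply(cuts, function(ct) sum(scores >= ct & labels == 0L),
                numeric(1)) / n_neg
  out <- data.frame(cutoff = c(Inf, cuts), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  class(out) <- c("ims_roc", "data.frame")
  out
}

trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' Closed-form approximation from the AUC value `A` and the group sizes:
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] /
#' (n_pos * n_neg)` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC value in `[0, 1]`.
#' @param n_pos,n_neg positive/negative group sizes.
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

# DeLong variance of the empirical AUC via placement values
delong_variance <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var(v10) / m + var(v01) / n
}

#' Confidence interval for an empirical AUC
#'
#' `"delong"` (default) uses the nonparametric covariance estimator of the
#' Mann-Whitney pair statistic; `"hanley_mcneil"` the closed-form variance
#' from [hanley_mcneil_se()]. Both give Wald intervals truncated to
#' `[0, 1]`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector; each class needs `>= 2` members.
#' @param level confidence level (default 0.95).
#' @param method `"delong"` or `"hanley_mcneil"`.
#' @return numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "hanley_mcneil")) {
  method <- match.arg(method)
  labels <- check_binary_scores(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 2L || n_neg < 2L) {
    abort_ims("each class needs at least 2 members", "imsvoc_input_error")
  }
  a <- auc(scores, labels)
  se <- if (method == "delong") {
    sqrt(max(delong_variance(scores, labels), 0))
  } else {
    hanley_mcneil_se(a, n_pos, n_neg)
  }
  z <- qnorm(1 - (1 - level) / 2)
  c(max(0, a - z * se), min(1, a + z * se))
}

#' Expected confidence-interval width for a planned ROC study
#'
#' Design-stage calculation: the width of a two-sided Wald interval for
#' the AUC, `2 * z * SE`, with the Hanley-McNeil standard error evaluated
#' at the anticipated AUC and group sizes. Used to choose sample sizes
#' before data collection (e.g. 123 cases and 62 controls at an
#' anticipated AUC of 0.87 give a 95% CI width of 0.10).
#'
#' @param auc anticipated AUC, in `[0.5, 1)` (design convention).
#' @param n_pos,n_neg planned group sizes, each `>= 2`.
#' @param level confidence level (default 0.95).
#' @return the expected CI width.
#' @examples
#' round(ci_width_for_design(0.87, 123, 62), 2)
#' @export
ci_width_for_design <- function(auc, n_pos, n_neg, level = 0.95) {
  if (auc < 0.5 || auc >= 1) {
    abort_ims("design AUC must lie in [0.5, 1)", "imsvoc_domain_error")
  }
  if (n_pos < 2 || n_neg < 2) {
    abort_ims("group sizes must be >= 2", "imsvoc_input_error")
  }
  2 * qnorm(1 - (1 - level) / 2) * hanley_mcneil_se(auc, n_pos, n_neg)
}

#' Two-sided p-value for AUC = 0.5
#'
#' Mann-Whitney rank-sum test of the score distributions of the two
#' classes, i.e. a test of no discrimination; identical to
#' [rank_sum_pvalue()] applied to the class-wise scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return two-sided p-value.
#' @export
auc_pvalue <- function(scores, labels) {
  labels <- check_binary_scores(scores, labels)
  rank_sum_pvalue(scores[labels == 1L], scores[labels == 0L])
}

#' Optimum cut-off by Youden's J
#'
#' Scans the ROC curve for the cutoff maximising `J = sensitivity +
#' specificity - 1`. J values within 1e-9 of the maximum count as tied;
#' ties are broken by higher specificity, then by lower cutoff.
#'
#' @param curve an `ims_roc` from [roc_curve()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutoff <- function(curve) {
  j <- curve$tpr - curve$fpr
  spec <- 1 - curve$fpr
  # J values within 1e-9 are ties (guards against floating-point noise in
  # rate arithmetic); then specificity desc, cutoff asc
  cand <- which(j >= max(j) - 1e-9)
  best <- cand[order(-spec[cand], curve$cutoff[cand])][1]
  list(cutoff = curve$cutoff[best], sensitivity = curve$tpr[best],
       specificity = spec[best], youden_j = j[best])
}

#' Confusion-matrix metrics at a fixed cutoff
#'
#' Predictions are `score >= cutoff`. Ratios with a zero denominator are
#' returned as `NaN`, never coerced to 0.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @param cutoff finite decision threshold.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv` and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  ratio <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  list(sensitivity = ratio(tp, fn), specificity = ratio(tn, fp),
       ppv = ratio(tp, fp), npv = ratio(tn, fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Diagnostic report from pooled out-of-fold probabilities
#'
#' Composes the full row of diagnostic statistics for one binary
#' comparison: AUC with 95% CI, the rank-sum p-value against AUC = 0.5,
#' the Youden-optimal cut-off and the sensitivity, specificity, PPV and
#' NPV observed there (predictive values use the study prevalence).
#'
#' @param cvresult an `ims_cv_result` from [run_cv()], or any numeric
#'   score vector.
#' @param labels binary 0/1 vector aligned with the scores.
#' @param ci_method `"delong"` (default) or `"hanley_mcneil"`.
#' @param level confidence level for the AUC interval.
#' @return an `ims_report` list: `auc`, `ci_low`, `ci_high`, `p_value`,
#'   `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`, `n_pos`,
#'   `n_neg`, `classifier`, `ci_method`.
#' @export
build_report <- function(cvresult, labels, ci_method = "delong",
                         level = 0.95) {
  scores <- if (inherits(cvresult, "ims_cv_result")) {
    cvresult$oof_probability
  } else {
    as.numeric(cvresult)
  }
  labels <- check_binary_scores(scores, labels)
  a <- auc(scores, labels)
  ci <- auc_ci(scores, labels, level = level, method = ci_method)
  curve <- roc_curve(scores, labels)
  oc <- optimal_cutoff(curve)
  cm <- confusion_metrics(scores, labels, oc$cutoff)
  structure(list(
    auc = a, ci_low = ci[1], ci_high = ci[2],
    p_value = auc_pvalue(scores, labels),
    cutoff = oc$cutoff,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv,
    n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
    classifier = if (inherits(cvresult, "ims_cv_result"))
      cvresult$classifier else NA_character_,
    ci_method = ci_method), class = "ims_report")
}

#' @export
print.ims_report <- function(x, ...) {
  cat(sprintf(
    "AUC (95%% CI): %.2f (%.2f-%.2f), p = %s\n", x$auc, x$ci_low,
    x$ci_high, format.pval(x$p_value, digits = 2)))
  cat(sprintf(
    "cut-off %.3g: sensitivity %.2f, specificity %.2f, PPV %.2f, NPV %.2f (n = %d/%d)\n",
    x$cutoff, x$sensitivity, x$specificity, x$ppv, x$npv, x$n_pos,
    x$n_neg))
  invisible(x)
}

#' One-row data frame view of a diagnostic report
#'
#' @param x an `ims_report`.
#' @param ... unused.
#' @return a one-row data frame in the usual table layout.
#' @export
as.data.frame.ims_report <- function(x, ...) {
  data.frame(classifier = x$classifier, auc = x$auc, ci_low = x$ci_low,
             ci_high = x$ci_high, sensitivity = x$sensitivity,
             specificity = x$specificity, ppv = x$ppv, npv = x$npv,
             p_value = x$p_value, cutoff = x$cutoff, n_pos = x$n_pos,
             n_neg = x$n_neg)
}
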