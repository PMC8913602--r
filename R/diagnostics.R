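# ROC analysis for count statistics: AUC in its Mann-Whitney form, a
# threshold-sweep curve, DeLong confidence intervals, Youden-index best
# thresholds and confusion-matrix indices. Scores are count statistics
# (high counts or C/T ratios); labels are the uncontrolled-BP reference.
# Predicted-positive always means score >= threshold.

check_scores_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    rlang::abort("`scores` and `labels` must have equal length.")
  }
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores))) {
    rlang::abort("`scores` and `labels` must be finite and non-missing.")
  }
  if (!any(labels) || all(labels)) {
    rlang::abort("degenerate labels: both classes must be present.")
  }
  labels
}

#' Area under the ROC curve (C-statistic)
#'
#' Computes the C-statistic of a score for a binary label as the
#' Mann-Whitney probability: over all (positive, negative) pairs the mean
#' of 1 if the positive scores higher, 1/2 on a tie, 0 otherwise. This is
#' identical to the trapezoidal area under the empirical ROC curve and is
#' computed here through midranks in O(n log n).
#'
#' @param scores Numeric scores; higher means more likely positive.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 = positive
#'   (uncontrolled).
#' @return A single number in \[0, 1\].
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # perfect separation
#' @export
auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores) # midranks: ties contribute 1/2 automatically
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components: placement values of each positive among
# the negatives and vice versa. Returns auc, se, and the components.
delong_components <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp) # one per positive
  v01 <- colMeans(cmp) # one per negative
  a <- mean(v10)
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = a, se = sqrt(max(s2, 0)), v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Wald interval `auc +/- z * se` where the standard error comes from the
#' DeLong structural-component variance estimator, clipped to \[0, 1\].
#' With perfect separation the variance is zero; the interval collapses to
#' `(auc, auc)` and a `degenerate` attribute is set (with a warning).
#'
#' @inheritParams auc
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `c(low, high)` with attributes `auc`, `se`,
#'   `method = "delong"` and `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_scores_labels(scores, labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    rlang::abort("DeLong CI needs at least 2 observations per class.")
  }
  comp <- delong_components(scores, labels)
  degenerate <- comp$se == 0
  if (degenerate) {
    rlang::warn("zero DeLong variance (perfect separation); CI collapses to the point estimate")
    ci <- c(comp$auc, comp$auc)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- pmin(pmax(comp$auc + c(-1, 1) * z * comp$se, 0), 1)
  }
  structure(stats::setNames(ci, c("low", "high")),
            auc = comp$auc, se = comp$se,
            method = "delong", degenerate = degenerate)
}

#' Empirical ROC curve
#'
#' Sweeps thresholds over the observed scores: the cutpoints are the
#' midpoints between consecutive distinct scores plus -Inf/+Inf sentinels,
#' with predicted-positive meaning score >= threshold. Sensitivity is
#' non-increasing and specificity non-decreasing along increasing
#' thresholds; the trapezoidal area equals [auc()].
#'
#' @inheritParams delong_ci
#' @param ci Attach a DeLong confidence interval for the AUC (default TRUE).
#' @return An object of class `hbp_roc`: list with `curve` (tibble of
#'   `threshold`, `sens`, `spec`), `auc`, `auc_ci`, `ci_method`, `n`,
#'   `n_positive`. `tidy()` returns the curve, `glance()` the AUC row,
#'   `autoplot()` draws the curve.
#' @export
roc_curve <- function(scores, labels, level = 0.95, ci = TRUE) {
  labels <- check_scores_labels(scores, labels)
  u <- sort(unique(scores))
  thresholds <- if (length(u) > 1) {
    c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  sens <- vapply(thresholds, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!labels] < t), numeric(1))
  auc_ci <- if (ci) delong_ci(scores, labels, level = level) else NULL
  structure(
    list(
      curve = tibble::tibble(threshold = thresholds, sens = sens, spec = spec),
      auc = auc(scores, labels),
      auc_ci = auc_ci,
      ci_method = if (ci) "delong" else NA_character_,
      n = length(scores),
      n_positive = sum(labels)
    ),
    class = "hbp_roc"
  )
}

#' @export
print.hbp_roc <- function(x, ...) {
  cat("<hbp_roc> n =", x$n, "(", x$n_positive, "positive )\n")
  cat("  AUC =", format(x$auc, digits = 4))
  if (!is.null(x$auc_ci)) {
    cat(" (", format(x$auc_ci[["low"]], digits = 4), "-",
        format(x$auc_ci[["high"]], digits = 4), ", ", x$ci_method, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Diagnostic indices at a fixed threshold
#'
#' Confusion-matrix indices of the rule "score >= cut": sensitivity,
#' specificity, PPV, NPV, correct classification rate (accuracy) and
#' Youden's J. PPV (NPV) is `NA` with `ppv_defined = FALSE`
#' (`npv_defined = FALSE`) when no case is predicted positive (negative).
#'
#' @inheritParams auc
#' @param cut Decision threshold; predicted positive when score >= cut.
#' @return One-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `ccr`, `youden_j`, `n`,
#'   `n_positive`, `ppv_defined`, `npv_defined`.
#' @examples
#' indices_at_threshold(c(14, 13, 6, 5), c(1, 1, 0, 0), cut = 12)
#' @export
indices_at_threshold <- function(scores, labels, cut) {
  labels <- check_scores_labels(scores, labels)
  pred <- scores >= cut
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv_defined <- (tp + fp) > 0
  npv_defined <- (tn + fn) > 0
  tibble::tibble(
    threshold = cut,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = spec,
    ppv = if (ppv_defined) tp / (tp + fp) else NA_real_,
    npv = if (npv_defined) tn / (tn + fn) else NA_real_,
    ccr = (tp + tn) / length(scores),
    youden_j = sens + spec - 1,
    n = length(scores),
    n_positive = tp + fn,
    ppv_defined = ppv_defined,
    npv_defined = npv_defined
  )
}

#' Best threshold by Youden's J
#'
#' Scans the ROC threshold grid (midpoints plus sentinels, see
#' [roc_curve()]) and returns the diagnostic indices at the threshold
#' maximising J = sensitivity + specificity - 1. Ties are broken toward
#' higher specificity, then toward the higher threshold; the tie-break is
#' recorded in the `tie_break` attribute.
#'
#' @inheritParams auc
#' @return One-row tibble as [indices_at_threshold()], at the argmax.
#' @export
best_threshold_youden <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  rc <- roc_curve(scores, labels, ci = FALSE)
  cur <- rc$curve[is.finite(rc$curve$threshold), , drop = FALSE]
  if (nrow(cur) == 0) { # single distinct score: only sentinel thresholds
    cur <- rc$curve
  }
  j <- cur$sens + cur$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[cur$spec[best] == max(cur$spec[best])]
    best <- best[which.max(cur$threshold[best])]
  }
  out <- indices_at_threshold(scores, labels, cut = cur$threshold[best])
  attr(out, "tie_break") <- "higher specificity, then higher threshold"
  out
}
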