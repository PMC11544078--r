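# ROC construction, AUC confidence intervals (DeLong / bootstrap),
# closest-topleft cut-off selection, confusion metrics and cut-off
# classification. Class 1 is "continental origin", class 0 the local
# immigration-area origin; a sample is called positive when its score is
# strictly greater than the threshold.

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  if (!any(labels == 0L) || !any(labels == 1L))
    stop("both classes must be present")
  labels
}

#' Build a ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores, with `-Inf` and `+Inf` sentinels. At threshold `c`, sensitivity
#' is the fraction of class-1 scores strictly above `c` and specificity the
#' fraction of class-0 scores at or below `c`. The AUC is computed by the
#' trapezoidal rule and equals the tie-corrected Mann-Whitney probability;
#' it is invariant under any strictly increasing transform of the scores,
#' so ratios and fitted logistic probabilities give identical curves.
#'
#' @param scores numeric scores (isotope ratios or model probabilities).
#' @param labels 0/1 class labels (1 = continental origin).
#' @return A list of class `"roc_result"`: `curve` (data frame with
#'   `threshold`, `sensitivity`, `specificity`), `auc` and the class counts
#'   `n0`, `n1`. Feed it to [cutoff_closest_topleft()] for the working
#'   threshold.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (anyNA(scores)) stop("missing scores not allowed")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  sens <- vapply(thr, function(ct) mean(pos > ct), numeric(1))
  spec <- vapply(thr, function(ct) mean(neg <= ct), numeric(1))
  # trapezoid over (FPR, TPR); thresholds ascending => FPR descending
  fpr <- 1 - spec
  auc <- sum(-diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, n0 = length(neg), n1 = length(pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, n0 = %d, n1 = %d, AUC = %.4f\n",
              nrow(x$curve), x$n0, x$n1, x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong placement components and AUC variance
delong_variance <- function(scores, labels) {
  labels <- check_labels(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(xi) mean(psi(xi, neg)), numeric(1))
  v01 <- vapply(neg, function(yj) mean(psi(pos, yj)), numeric(1))
  auc <- mean(v10)
  list(auc = auc,
       var = var(v10) / length(pos) + var(v01) / length(neg))
}

#' Confidence interval for the AUC
#'
#' DeLong's asymptotic variance-based interval (default) or a seeded
#' stratified bootstrap percentile interval. Both are truncated to `[0, 1]`.
#'
#' @param scores,labels as in [roc_curve()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return A list with `auc`, `lower`, `upper`, `method`, and for DeLong the
#'   asymptotic `se`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   conf = 0.95, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  labels <- check_labels(labels)
  if (method == "delong") {
    d <- delong_variance(scores, labels)
    z <- qnorm(1 - (1 - conf) / 2)
    se <- sqrt(d$var)
    lo <- max(0, d$auc - z * se); hi <- min(1, d$auc + z * se)
    list(auc = d$auc, lower = lo, upper = hi, se = se, method = "delong")
  } else {
    if (!is.null(seed)) set.seed(seed)
    i0 <- which(labels == 0L); i1 <- which(labels == 1L)
    reps <- vapply(seq_len(n_boot), function(k) {
      idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
      roc_curve(scores[idx], labels[idx])$auc
    }, numeric(1))
    qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    list(auc = roc_curve(scores, labels)$auc,
         lower = max(0, qs[1]), upper = min(1, qs[2]),
         method = "bootstrap", n_boot = n_boot)
  }
}

#' Closest-topleft cut-off of a ROC curve
#'
#' Returns the threshold minimizing the squared distance to the top-left
#' corner of the ROC plane, `(1 - sensitivity)^2 + (1 - specificity)^2`.
#' Ties break toward the LOWER threshold, so borderline samples are called
#' non-local -- the conservative choice when the aim is detecting
#' immigration. The chosen cut-off is stored in the returned `roc_result`.
#'
#' @param roc a [roc_curve()] result.
#' @return The cut-off threshold (numeric scalar) with attributes
#'   `"sensitivity"`, `"specificity"` and `"distance"` giving the operating
#'   point attained there.
#' @export
cutoff_closest_topleft <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  d <- (1 - roc$curve$sensitivity)^2 + (1 - roc$curve$specificity)^2
  i <- which(d == min(d))[1]  # thresholds ascending: first tie = lowest
  structure(roc$curve$threshold[i],
            sensitivity = roc$curve$sensitivity[i],
            specificity = roc$curve$specificity[i],
            distance = d[i])
}

#' Confusion metrics at a cut-off
#'
#' Class 1 is called when `score > cutoff`. Returns sensitivity,
#' specificity, positive and negative predictive values as percentages from
#' the 2x2 table; a predictive value whose denominator cell is empty is
#' `NA` and flagged.
#'
#' @param scores,labels as in [roc_curve()].
#' @param cutoff finite threshold.
#' @return A list of class `"confusion_metrics"` with the four percentages,
#'   the 2x2 counts (`tp`, `fn`, `tn`, `fp`) and `undefined` naming any
#'   undefined predictive values.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- check_labels(labels)
  stopifnot(is.finite(cutoff))
  pred <- scores > cutoff
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  fp <- sum(pred & labels == 0L); tn <- sum(!pred & labels == 0L)
  pv <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  undef <- c(if (tp + fp == 0) "ppv", if (tn + fn == 0) "npv")
  structure(list(sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 ppv = pv(tp, tp + fp), npv = pv(tn, tn + fn),
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 undefined = undef),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  cat(sprintf("  2x2: TP %d, FN %d, TN %d, FP %d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Classify measurements against a ratio cut-off
#'
#' Strict inequality: a sample is `above_cutoff` iff its ratio is strictly
#' greater than the cut-off; a ratio exactly at the cut-off is
#' `at_or_below_cutoff` (presumed local / low-ratio origin).
#'
#' @param ratios numeric ratios, or a data frame with a `ratio` column (and
#'   optionally `sample_id`).
#' @param cutoff finite ratio cut-off.
#' @param sample_id optional ids (recycled against `ratios`).
#' @return Data frame `sample_id`, `ratio`, `cutoff`, `call` with `call` a
#'   factor in `c("above_cutoff", "at_or_below_cutoff")`.
#' @export
classify_by_cutoff <- function(ratios, cutoff, sample_id = NULL) {
  if (is.data.frame(ratios)) {
    if (is.null(sample_id) && "sample_id" %in% names(ratios))
      sample_id <- ratios$sample_id
    ratios <- ratios$ratio
  }
  stopifnot(is.finite(cutoff))
  if (is.null(sample_id)) sample_id <- seq_along(ratios)
  call <- ifelse(ratios > cutoff, "above_cutoff", "at_or_below_cutoff")
  data.frame(sample_id = sample_id, ratio = ratios, cutoff = cutoff,
             call = factor(call, levels = c("above_cutoff",
                                            "at_or_below_cutoff")))
}
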