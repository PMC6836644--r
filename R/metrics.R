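#' Confusion matrices for Active/Inactive classification
#'
#' `confusion_matrix()` tabulates predictions against truth with
#' `"Active"` as the positive class; `confusion_from_counts()` builds the
#' same object from the four counts directly (e.g. when reproducing a
#' published table).
#'
#' @param truth,predicted character vectors of `"Active"`/`"Inactive"`
#'   labels of equal length.
#' @return an object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
#' @examples
#' cm <- confusion_from_counts(tp = 474, fp = 3, tn = 475, fn = 30)
#' mcc(cm)
#' ppv(cm)
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length (%d vs %d)",
          length(truth), length(predicted))
  }
  if (length(truth) == 0) abort("cannot build a confusion matrix from zero labels")
  check_labels(truth, allow_unknown = FALSE, what = "truth label")
  check_labels(predicted, allow_unknown = FALSE, what = "predicted label")
  confusion_from_counts(
    tp = sum(truth == "Active" & predicted == "Active"),
    fp = sum(truth == "Inactive" & predicted == "Active"),
    tn = sum(truth == "Inactive" & predicted == "Inactive"),
    fn = sum(truth == "Active" & predicted == "Inactive")
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (!all(vapply(counts, is_count, TRUE)) || any(counts < 0)) {
    abort("confusion-matrix counts must be non-negative integers")
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$fp + cm$tn + cm$fn

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(FN+TN)(FP+TN)(TP+FN)}}}
#'
#' MCC lies in \[-1, 1\]: 1 means no classification errors, -1 means every
#' instance was misclassified, 0 means the prediction is uncorrelated with
#' the truth. When any marginal factor of the denominator is zero the
#' coefficient is undefined and the standard convention of returning 0 is
#' applied.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric scalar in \[-1, 1\].
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm_total(cm) == 0) abort("empty confusion matrix")
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  den2 <- (tp + fp) * (fn + tn) * (fp + tn) * (tp + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Positive predictive value
#'
#' `PPV = TP / (TP + FP)`: the posterior probability that a compound
#' predicted Active is truly Active. Note that PPV alone is gameable — a
#' classifier that labels a single true active as its only positive
#' reaches PPV = 1 — so it should be read alongside MCC. The degenerate
#' case TP + FP = 0 (no positive predictions at all) returns 0 with a
#' warning instead of failing, so screening sweeps never abort.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric scalar in \[0, 1\].
#' @export
ppv <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp == 0) {
    warning("no positive predictions: PPV undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  cm$tp / (cm$tp + cm$fp)
}

#' Overall accuracy
#'
#' `(TP + TN) / total`: the overall probability of a correct
#' classification.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric scalar in \[0, 1\].
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm_total(cm)
  if (total == 0) abort("empty confusion matrix")
  (cm$tp + cm$tn) / total
}

#' Total number of misclassification errors
#'
#' `FP + FN`.
#'
#' @param cm a [confusion_matrix()].
#' @return non-negative integer.
#' @export
error_count <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cm$fp + cm$fn
}

#' Percent reduction in false positives
#'
#' `100 * (FP_ref - FP_reduced) / FP_ref`: how much of the reference
#' model's false-positive burden the reduced model removes.
#'
#' @param cm_reduced,cm_reference [confusion_matrix()] objects; the
#'   reference must have at least one false positive.
#' @return percentage (may be negative if the "reduced" model is worse).
#' @export
#' @examples
#' fp_reduction_percent(confusion_from_counts(474, 3, 475, 30),
#'                      confusion_from_counts(480, 60, 418, 24))  # 95
fp_reduction_percent <- function(cm_reduced, cm_reference) {
  stopifnot(inherits(cm_reduced, "confusion_matrix"),
            inherits(cm_reference, "confusion_matrix"))
  if (cm_reference$fp == 0) {
    abort("reference confusion matrix has no false positives")
  }
  100 * (cm_reference$fp - cm_reduced$fp) / cm_reference$fp
}

#' Summary metrics for a set of predictions
#'
#' Convenience wrapper computing the confusion matrix and all scalar
#' metrics used by the pipeline reports.
#'
#' @param truth,predicted label vectors (see [confusion_matrix()]).
#' @return list with `confusion`, `mcc`, `ppv`, `accuracy`, `errors`.
#' @export
classification_report <- function(truth, predicted) {
  cm <- confusion_matrix(truth, predicted)
  list(confusion = cm, mcc = mcc(cm),
       ppv = suppressWarnings(ppv(cm)),
       accuracy = accuracy(cm), errors = error_count(cm))
}
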