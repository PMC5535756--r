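# Evaluation: confusion counts, the six summary metrics, and PR/ROC
# curves with trapezoidal areas.  The abnormal (HCC) class is the positive
# class throughout, so sensitivity is the proportion of abnormal patches
# correctly recognised.

#' Confusion counts
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @param positive Positive class (default `"abnormal"`).
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = "abnormal") {
  truth <- as_class_factor(truth)
  pred <- as_class_factor(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred must be aligned", call. = FALSE)
  }
  pos <- truth == positive
  hit <- pred == truth
  structure(list(TP = sum(pos & hit), TN = sum(!pos & hit),
                 FP = sum(!pos & !hit), FN = sum(pos & !hit)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Summary classification metrics
#'
#' Accuracy, sensitivity (= recall), specificity, precision, recall and
#' F1.  A metric whose denominator is zero is reported as `NA`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector `ACC`, `SEN`, `SPE`, `P`, `R`, `F1`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(rep(c("normal", "abnormal"), 5),
#'                                  rep("abnormal", 10)))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  p <- frac(tp, tp + fp)
  r <- frac(tp, tp + fn)
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
        else NA_real_
  c(ACC = (tp + tn) / total, SEN = r, SPE = frac(tn, tn + fp),
    P = p, R = r, F1 = f1)
}

#' PR and ROC curves by threshold sweep
#'
#' Sweeps the unique abnormal-class scores as decision thresholds
#' (`score >= threshold` predicts abnormal; tied scores share one
#' threshold), computes TPR/FPR and precision/recall at each, and the
#' trapezoidal areas under both curves.  The ROC curve always includes the
#' endpoints (0, 0) and (1, 1).
#'
#' @param scores Numeric abnormal-class scores.
#' @param labels True class labels (both classes must be present).
#' @return Object of class `curve_data`: list with data frames `roc`
#'   (`threshold`, `FPR`, `TPR`) and `pr` (`threshold`, `recall`,
#'   `precision`), plus `auc_roc` and `auc_pr`.
#' @export
classification_curves <- function(scores, labels) {
  labels <- as_class_factor(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must be aligned", call. = FALSE)
  }
  if (!all(.class_levels %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- labels == "abnormal"
  np <- sum(pos); nn <- sum(!pos)
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(pos & scores >= t), numeric(1))
  fp <- vapply(th, function(t) sum(!pos & scores >= t), numeric(1))
  tpr <- tp / np
  fpr <- fp / nn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  roc <- data.frame(threshold = c(Inf, th, -Inf),
                    FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
  pr <- data.frame(threshold = c(Inf, th),
                   recall = c(0, tpr), precision = c(1, prec))
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(roc = roc, pr = pr,
                 auc_roc = trapz(roc$FPR, roc$TPR),
                 auc_pr = trapz(pr$recall, pr$precision)),
            class = "curve_data")
}

#' @export
print.curve_data <- function(x, ...) {
  cat(sprintf("curves: AUC-ROC = %.4f, AUC-PR = %.4f (%d thresholds)\n",
              x$auc_roc, x$auc_pr, nrow(x$pr) - 1L))
  invisible(x)
}
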