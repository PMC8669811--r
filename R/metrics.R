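#' Confusion-matrix classification metrics
#'
#' Computes the confusion counts and the four standard binary-classification
#' measures from hard predictions:
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP),}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' When any factor of the MCC denominator is zero, MCC is reported as 0
#' (the conventional value for a degenerate confusion matrix).
#'
#' @param labels Binary 0/1 vector of true classes (both classes required
#'   for SN and SP to be defined).
#' @param predicted Binary 0/1 vector of predicted classes.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(labels, predicted) {
  labels <- check_binary_label(labels)
  predicted <- check_binary_label(predicted)
  if (length(labels) != length(predicted)) {
    abort("labels and predictions have different lengths")
  }
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / length(labels),
    mcc = mcc
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values to trace
#' the ROC curve (false-positive rate vs true-positive rate) and computes
#' the area under it by the trapezoidal rule. Tied scores are grouped into
#' a single curve vertex, which makes the trapezoidal area equal to the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted half.
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric score vector (higher = more positive).
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc` (scalar in \[0, 1\]).
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))$auc  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  labels <- check_binary_label(labels)
  if (length(labels) != length(scores)) {
    abort("labels and scores have different lengths")
  }
  if (any(is.na(scores))) abort("scores contain NA")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined with a single class in the labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores into single threshold steps
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp_cum <- cumsum(y == 1)[last_of_tie]
  fp_cum <- cumsum(y == 0)[last_of_tie]
  roc <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp_cum / n_neg),
    tpr = c(0, tp_cum / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report from scores
#'
#' Combines the thresholded confusion metrics with the ROC curve and AUC
#' into one evaluation report. The hard label is `score >= threshold`
#' (default 0.5 on the positive-class vote fraction).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the positive-class score.
#' @return An object of class `aip_eval`: a list with the confusion counts,
#'   `sn`, `sp`, `acc`, `mcc`, `auc`, `threshold`, `n` and the `roc` tibble.
#' @export
eval_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion_metrics(labels, as.integer(scores >= threshold))
  ra <- roc_auc(labels, scores)
  structure(
    c(as.list(cm), list(auc = ra$auc, threshold = threshold,
                        n = length(labels), roc = ra$roc)),
    class = "aip_eval"
  )
}

#' @export
print.aip_eval <- function(x, ...) {
  cat("Evaluation report (n = ", x$n, ", threshold = ", x$threshold, ")\n",
      sep = "")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  SN %.3f  SP %.3f  ACC %.3f  MCC %.3f  AUC %.3f\n",
              x$sn, x$sp, x$acc, x$mcc, x$auc))
  invisible(x)
}

#' @describeIn eval_report one-row tibble of the summary metrics.
#' @param x,object An `aip_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.aip_eval <- function(x, ...) {
  tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc,
         auc = x$auc, threshold = x$threshold, n = x$n)
}

#' @describeIn eval_report ROC points as a tibble (`threshold`, `fpr`, `tpr`).
#' @exportS3Method generics::tidy
tidy.aip_eval <- function(x, ...) {
  x$roc
}

#' @describeIn eval_report ROC curve plot.
#' @exportS3Method ggplot2::autoplot
autoplot.aip_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - SP)",
      y = "True-positive rate (SN)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    )
}

#' Serialize an evaluation report to JSON
#'
#' Writes the confusion counts, summary metrics and ROC points as JSON.
#' Output is deterministic: identical reports produce byte-identical files.
#'
#' @param report An `aip_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "aip_eval"))
  payload <- report
  class(payload) <- NULL
  payload$roc <- as.data.frame(payload$roc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
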