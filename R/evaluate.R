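#' Confusion matrix at a decision threshold
#'
#' "Accepted" is the positive class throughout; an image is predicted
#' Accepted when its probability is strictly greater than the threshold (so a
#' threshold of 1 rejects everything).
#'
#' @param labels ground-truth labels (`"Accepted"`/`"Rejected"`).
#' @param probabilities acceptance probabilities, same length.
#' @param threshold decision threshold in \[0, 1\].
#' @return a `confusion_matrix`: counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) {
    .stopf("`labels` and `probabilities` must have equal length")
  }
  labels <- normalize_labels(labels)
  pred_pos <- probabilities > threshold
  truth_pos <- labels == "Accepted"
  confusion_matrix(tp = sum(pred_pos & truth_pos),
                   fp = sum(pred_pos & !truth_pos),
                   fn = sum(!pred_pos & truth_pos),
                   tn = sum(!pred_pos & !truth_pos))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative counts (Accepted = positive).
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("label Rejected", "label Accepted"),
                              c("pred Rejected", "pred Accepted")))
  print(m)
  invisible(x)
}

#' Classification metrics of a confusion matrix
#'
#' Accuracy is (tp + tn) / total; precision tp / (tp + fp); recall
#' tp / (tp + fn). A zero denominator yields `NA` (undefined), never a
#' number.
#'
#' @param cm a `confusion_matrix`.
#' @name metrics
NULL

#' @rdname metrics
#' @export
accuracy <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) return(NA_real_)
  (cm$tp + cm$tn) / n
}

#' @rdname metrics
#' @export
precision <- function(cm) {
  d <- cm$tp + cm$fp
  if (d == 0) return(NA_real_)
  cm$tp / d
}

#' @rdname metrics
#' @export
recall <- function(cm) {
  d <- cm$tp + cm$fn
  if (d == 0) return(NA_real_)
  cm$tp / d
}

roc_points <- function(labels, probabilities) {
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2) {
    .stopf("both classes must be present")
  }
  ord <- order(probabilities, decreasing = TRUE)
  y <- labels[ord] == "Accepted"
  s <- probabilities[ord]
  n_pos <- sum(y); n_neg <- sum(!y)
  # group tied scores: one operating point per distinct score value. The
  # point counting all scores >= s_i is realized (under the strict
  # p > threshold rule) by thresholds in [s_{i+1}, s_i); it is labelled with
  # the smallest threshold realizing it, the next lower distinct score.
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  distinct <- s[last]
  data.frame(threshold = c(distinct[-1], -Inf), tp = tp, fp = fp,
             fn = n_pos - tp, tn = n_neg - fp)
}

#' ROC curve and AUC
#'
#' True positive rate against false positive rate over all distinct decision
#' thresholds (prediction rule: probability > threshold; ties grouped). AUC
#' by trapezoidal integration.
#'
#' @inheritParams confusion
#' @return data frame with `threshold`, `fpr`, `tpr`, including the (0,0)
#'   and (1,1) endpoints; the AUC is attached as attribute `"auc"`.
#' @export
roc_curve <- function(labels, probabilities) {
  pts <- roc_points(labels, probabilities)
  n_pos <- pts$tp[nrow(pts)] + pts$fn[nrow(pts)]
  n_neg <- pts$fp[nrow(pts)] + pts$tn[nrow(pts)]
  # the last point (threshold below every score) is always (1, 1)
  out <- data.frame(threshold = c(Inf, pts$threshold),
                    fpr = c(0, pts$fp / n_neg),
                    tpr = c(0, pts$tp / n_pos))
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  attr(out, "auc") <- auc
  out
}

#' Precision-recall curve
#'
#' One point per distinct threshold (ties grouped), plus the all-positive
#' endpoint whose precision equals the class prevalence.
#'
#' @inheritParams confusion
#' @return data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, probabilities) {
  pts <- roc_points(labels, probabilities)
  n_pos <- pts$tp[nrow(pts)] + pts$fn[nrow(pts)]
  keep <- pts$tp + pts$fp > 0
  pts <- pts[keep, , drop = FALSE]
  data.frame(threshold = pts$threshold,
             recall = pts$tp / n_pos,
             precision = pts$tp / (pts$tp + pts$fp))
}

#' Choose the decision threshold that reaches a precision target
#'
#' The smallest threshold whose precision is at least `target` -- i.e. the
#' best achievable recall subject to the precision constraint.
#'
#' @inheritParams confusion
#' @param target precision target, default 0.97.
#' @return an `operating_point`: `threshold`, `precision`, `recall`.
#' @export
select_threshold_for_precision <- function(labels, probabilities,
                                           target = 0.97) {
  pc <- pr_curve(labels, probabilities)
  ok <- pc$precision >= target
  if (!any(ok)) {
    .stopf("precision target %.3f is unachievable (maximum achievable: %.3f)",
           target, max(pc$precision))
  }
  i <- which(ok)[which.min(pc$threshold[ok])]
  structure(list(threshold = pc$threshold[i], precision = pc$precision[i],
                 recall = pc$recall[i]),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.3f: precision %.3f, recall %.3f\n",
              x$threshold, x$precision, x$recall))
  invisible(x)
}

#' Precision stratified by track count
#'
#' @inheritParams confusion
#' @param track_counts tracks per image, same length as `labels`.
#' @param breaks bin edges covering the observed counts.
#' @param threshold decision threshold.
#' @return data frame with one row per bin: `bin`, `n`, `precision` (`NA`
#'   where undefined).
#' @export
stratified_precision <- function(labels, probabilities, track_counts,
                                 breaks, threshold = 0.5) {
  bins <- cut(track_counts, breaks = breaks, include.lowest = TRUE)
  if (anyNA(bins)) .stopf("`breaks` must cover all observed track counts")
  rows <- lapply(levels(bins), function(b) {
    i <- bins == b
    data.frame(bin = b, n = sum(i),
               precision = if (any(i)) {
                 precision(confusion(labels[i], probabilities[i], threshold))
               } else NA_real_)
  })
  do.call(rbind, rows)
}

#' Project precision and recall onto an expected confusion matrix
#'
#' For a batch of `n_positive` adequate and `n_negative` inadequate images,
#' the expected integer counts at the given operating point:
#' tp = round(recall x n_positive), fn the remainder,
#' fp = round(tp x (1 - precision) / precision), tn the remainder. Rounding
#' is to the nearest integer, ties away from zero.
#'
#' @param precision,recall operating-point metrics in (0, 1\].
#' @param n_positive,n_negative batch composition.
#' @return a `confusion_matrix`. If the implied fp exceeds `n_negative` the
#'   inputs are inconsistent and an error is raised.
#' @export
project_confusion <- function(precision, recall, n_positive, n_negative) {
  stopifnot(precision > 0, precision <= 1, recall > 0, recall <= 1,
            n_positive >= 0, n_negative >= 0)
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  tp <- half_away(recall * n_positive)
  fn <- n_positive - tp
  fp <- half_away(tp * (1 - precision) / precision)
  if (fp > n_negative) {
    .stopf("inconsistent inputs: implied fp (%d) exceeds n_negative (%d)",
           fp, n_negative)
  }
  tn <- n_negative - fp
  confusion_matrix(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-class histograms of predicted probabilities
#'
#' @inheritParams confusion
#' @param breaks probability bin edges.
#' @return list with `breaks`, `accepted` and `rejected` bin counts.
#' @export
prediction_histogram <- function(labels, probabilities,
                                 breaks = seq(0, 1, 0.1)) {
  labels <- normalize_labels(labels)
  count <- function(p) {
    if (length(p) == 0) return(integer(length(breaks) - 1))
    hist(pmin(pmax(p, min(breaks)), max(breaks)), breaks = breaks,
         plot = FALSE)$counts
  }
  list(breaks = breaks,
       accepted = count(probabilities[labels == "Accepted"]),
       rejected = count(probabilities[labels == "Rejected"]))
}
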