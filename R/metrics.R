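# Confusion-matrix metrics and ROC / precision-recall areas.

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/N`, `F1 = 2*P*R/(P+R)`. A zero denominator yields 0
#' and sets the `degenerate` flag.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return named list `precision, recall, accuracy, f1, degenerate`.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) format_error("confusion counts must be non-negative")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn)
  f1 <- f1_score(precision, recall)
  if (precision + recall == 0) degenerate <- TRUE
  list(precision = precision, recall = recall, accuracy = accuracy, f1 = f1,
       degenerate = degenerate)
}

#' Harmonic F1 from precision and recall
#' @param precision,recall rates in `[0, 1]`.
#' @return `2*P*R/(P+R)`, or 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Areas under the ROC and precision-recall curves
#'
#' AUROC by trapezoidal integration of the tie-aware FPR/TPR staircase
#' (equivalent to the Mann-Whitney U statistic with ties counted one half).
#' AUPRC by right-continuous stepwise integration of the PR curve
#' (precision at each distinct threshold times the recall increment).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @return named list `auroc, auprc`.
#' @export
roc_pr_areas <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    degenerate_input_error("both classes must be present to compute ROC/PR areas")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct-score threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  prec <- tp / (tp + fp); rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}
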