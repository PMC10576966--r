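# Evaluation metrics: confusion-matrix summaries and ROC AUC.

#' Confusion-matrix metrics
#'
#' Specificity \code{TN/(TN+FP)}, sensitivity \code{TP/(TP+FN)}, accuracy
#' and the Matthews correlation coefficient
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}. A zero
#' factor in the MCC denominator yields MCC 0 by convention; an undefined
#' Sp or Sn (empty class) yields 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (total > 0).
#' @return named vector \code{c(sp, sn, acc, mcc)}.
#' @examples
#' confusionMetrics(9, 8, 2, 1)
#' @export
confusionMetrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
  sn <- if (tp + fn == 0) 0 else tp / (tp + fn)
  acc <- (tp + tn) / total
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(sp = sp, sn = sn, acc = acc, mcc = mcc)
}

# normalize labels to logical is-positive
.isPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) return(labels == 1)
  labels %in% c("positive", "1", "TRUE", "pos")
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' The probability that a uniformly chosen positive sample receives a
#' higher score than a uniformly chosen negative one, ties counting one
#' half — identical to the area under the empirical ROC curve traced over
#' all thresholds.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels class labels (\code{"positive"}/\code{"negative"},
#'   logical, or 0/1).
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  pos <- .isPositive(labels)
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' ROC curve points
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @return data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold}.
#' @export
rocCurve <- function(scores, labels) {
  pos <- .isPositive(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !pos) / max(1, sum(!pos)),
      tpr = sum(pred & pos) / max(1, sum(pos)))
  }, c(fpr = 0, tpr = 0)))
  data.frame(fpr = out[, 1], tpr = out[, 2], threshold = th)
}

# assemble an EvalReport from pooled predictions
.evalReport <- function(prob, truthPos, folds = data.frame(),
                        threshold = 0.5) {
  pred <- prob >= threshold
  tp <- sum(pred & truthPos); tn <- sum(!pred & !truthPos)
  fp <- sum(pred & !truthPos); fn <- sum(!pred & truthPos)
  m <- confusionMetrics(tp, tn, fp, fn)
  new("EvalReport", tp = tp, tn = tn, fp = fp, fn = fn,
      sp = m[["sp"]], sn = m[["sn"]], acc = m[["acc"]], mcc = m[["mcc"]],
      auc = rocAuc(prob, truthPos), folds = folds)
}
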