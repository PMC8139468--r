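## Evaluation metrics: confusion matrix, accuracy, Minimum Sensitivity, AUC.
## Graft survival is the positive class throughout.

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn counts; survival is the positive class.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(tp, fn, fp, tn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fn = as.numeric(fn),
      fp = as.numeric(fp), tn = as.numeric(tn))
}

#' Confusion matrix from scores at a probability threshold
#'
#' @param labels binary labels, 1 = survival.
#' @param scores predicted survival probabilities.
#' @param threshold classification cut-off (default 0.5).
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromScores <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  confusionMatrix(tp = sum(pred == 1 & labels == 1),
                  fn = sum(pred == 0 & labels == 1),
                  fp = sum(pred == 1 & labels == 0),
                  tn = sum(pred == 0 & labels == 0))
}

#' Minimum Sensitivity
#'
#' The smaller of the two per-class recalls,
#' `min(TP/(TP+FN), TN/(TN+FP))`. On imbalanced end-points a trivial
#' majority-class model scores high accuracy but MS = 0, which is why the
#' benchmark selects models by MS.
#'
#' @param x a [ConfusionMatrix-class] or an [EvalResult-class].
#' @return value in \[0, 1\].
#' @examples
#' minimumSensitivity(confusionMatrix(30, 70, 10, 90))   # min(0.3, 0.9)
#' @export
setMethod("minimumSensitivity", "ConfusionMatrix", function(x) {
  if (x@tp + x@fn == 0)
    stop("no examples of the survival class; sensitivity undefined",
         call. = FALSE)
  if (x@tn + x@fp == 0)
    stop("no examples of the non-survival class; specificity undefined",
         call. = FALSE)
  min(x@tp / (x@tp + x@fn), x@tn / (x@tn + x@fp))
})

#' @rdname minimumSensitivity
#' @export
setMethod("minimumSensitivity", "EvalResult", function(x) x@ms)

#' Accuracy
#'
#' @param x a [ConfusionMatrix-class] or an [EvalResult-class].
#' @return fraction of correct predictions.
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x) {
  tot <- x@tp + x@fn + x@fp + x@tn
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  (x@tp + x@tn) / tot
})

#' @rdname accuracy
#' @export
setMethod("accuracy", "EvalResult", function(x) x@acc)

#' @describeIn ConfusionMatrix-class total number of evaluated pairs.
#' @param x a `ConfusionMatrix`.
#' @export
setMethod("length", "ConfusionMatrix", function(x)
  as.integer(x@tp + x@fn + x@fp + x@tn))

#' Sum confusion matrices across folds
#'
#' @param cms list of [ConfusionMatrix-class] objects.
#' @return the pooled [ConfusionMatrix-class].
#' @export
poolConfusion <- function(cms) {
  confusionMatrix(tp = sum(vapply(cms, function(c) c@tp, numeric(1))),
                  fn = sum(vapply(cms, function(c) c@fn, numeric(1))),
                  fp = sum(vapply(cms, function(c) c@fp, numeric(1))),
                  tn = sum(vapply(cms, function(c) c@tn, numeric(1))))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random survivor
#' receives a higher score than a uniformly random non-survivor, ties counted
#' one half. Invariant under any strictly increasing transform of the scores.
#'
#' @param scores predicted survival scores.
#' @param labels binary labels, 1 = survival.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))   # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate scores against labels
#'
#' @inheritParams confusionFromScores
#' @param wallTime elapsed seconds to report (informational).
#' @return an [EvalResult-class] bundling the confusion matrix, accuracy,
#'   Minimum Sensitivity and AUC.
#' @export
evaluateScores <- function(labels, scores, threshold = 0.5, wallTime = NA_real_) {
  cm <- confusionFromScores(labels, scores, threshold)
  new("EvalResult", cm = cm, acc = accuracy(cm),
      ms = minimumSensitivity(cm), auc = aucScore(scores, labels),
      wallTime = as.numeric(wallTime))
}

#' @describeIn ConfusionMatrix-class 2x2 display.
#' @param object a `ConfusionMatrix`.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(c("true survival", "true non-survival"),
                              c("pred survival", "pred non-survival")))
  print(m)
})

#' @describeIn EvalResult-class one-line metric summary.
#' @param object an `EvalResult`.
#' @export
setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: Acc %.3f | MS %.3f | AUC %.3f  (n = %d)\n",
              object@acc, object@ms, object@auc, length(object@cm)))
})
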