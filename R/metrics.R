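#' Confusion matrix from scores at a decision threshold
#'
#' @param scores predicted positive-class probabilities.
#' @param labels true 0/1 labels (1 = pulmonary-sarcoidosis-like class).
#' @param threshold decision threshold (default 0.5).
#' @return a [ConfusionMatrix].
#' @export
confusionFromScores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  ConfusionMatrix(tp = sum(pred == 1L & labels == 1L),
                  tn = sum(pred == 0L & labels == 0L),
                  fp = sum(pred == 1L & labels == 0L),
                  fn = sum(pred == 0L & labels == 1L))
}

#' The five diagnostic metrics of a confusion matrix
#'
#' Sensitivity (= recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/(TP+TN+FP+FN), and
#' F1 = 2 * precision * recall / (precision + recall). A metric whose
#' denominator is zero is reported as NA (undefined).
#'
#' @param cm a [ConfusionMatrix] or named vector with tp, tn, fp, fn.
#' @return named numeric(5): sensitivity, specificity, precision,
#'   accuracy, f1.
#' @examples
#' computeMetrics(ConfusionMatrix(tp = 8, tn = 6, fp = 4, fn = 2))
#' @export
computeMetrics <- function(cm) {
  if (is(cm, "ConfusionMatrix")) {
    tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  } else {
    tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  }
  n <- tp + tn + fp + fn
  if (n == 0) stop("computeMetrics: empty confusion matrix")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  acc <- (tp + tn) / n
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, f1 = f1)
}

#' Row-normalized (per-true-class) confusion rates
#'
#' @param cm a [ConfusionMatrix].
#' @return 2 x 2 matrix of rates; rows = true class (positive, negative),
#'   columns = predicted class (positive, negative).
#' @export
normalizedConfusion <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- matrix(c(cm@tp, cm@fn, cm@fp, cm@tn), 2, 2, byrow = TRUE,
              dimnames = list(true = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  sweep(m, 1, pmax(rowSums(m), 1), "/")
}

#' Area under the pooled ROC curve
#'
#' Trapezoidal AUC of the ROC built from scores pooled across
#' cross-validation folds (the combined AUC); equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores predicted probabilities.
#' @param labels true 0/1 labels.
#' @return numeric AUC in [0, 1].
#' @export
pooledAUC <- function(scores, labels) {
  stopifnot(length(unique(labels)) == 2L)
  as.numeric(pROC::auc(response = labels, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Pooled ROC curve points
#'
#' @param scores,labels as in [pooledAUC()].
#' @return data.frame with specificity and sensitivity columns along the
#'   ROC curve.
#' @export
rocPoints <- function(scores, labels) {
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  data.frame(specificity = r$specificities, sensitivity = r$sensitivities)
}
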