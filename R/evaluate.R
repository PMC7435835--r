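## Per-minute evaluation: confusion matrix, accuracy / sensitivity /
## specificity (apnea = positive class, reported in % to one decimal),
## ROC curve and trapezoidal AUC.

## Half-up rounding to `digits` decimals (plain round() rounds half to
## even, which disagrees with reported-literature conventions at .x5).
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Confusion matrix of per-minute predictions
#'
#' Counts with apnea (`"A"`) as the positive class. The four counts
#' partition the input.
#'
#' @param labels,predictions equal-length character vectors over
#'   `c("N", "A")`.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionCounts(c("A", "A", "N"), c("A", "N", "N"))
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop(sprintf("length mismatch: %d labels vs %d predictions",
                 length(labels), length(predictions)))
  bad <- setdiff(unique(c(labels, predictions)), .LABEL_LEVELS)
  if (length(bad))
    stop("labels/predictions outside {N, A}: ", paste(bad, collapse = ", "))
  confusionMatrix(
    TP = sum(labels == "A" & predictions == "A"),
    FP = sum(labels == "N" & predictions == "A"),
    TN = sum(labels == "N" & predictions == "N"),
    FN = sum(labels == "A" & predictions == "N"))
}

#' Accuracy, sensitivity and specificity in percent
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, each times 100 and rounded half-up to
#' one decimal (the reporting convention of the apnea-detection
#' literature). A zero denominator yields `NaN` for that metric with an
#' `"undefined"` attribute naming it, never a silent zero.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param digits decimals to keep (default 1); `NA` to skip rounding.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity` (percent).
#' @examples
#' classificationMetrics(confusionMatrix(TP = 5287, FP = 854,
#'                                       TN = 9863, FN = 1230))
#' # accuracy 87.9, sensitivity 81.1, specificity 92.0
#' @export
classificationMetrics <- function(cm, digits = 1) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@TP; fp <- cm@FP; tn <- cm@TN; fn <- cm@FN
  den <- c(accuracy = tp + fp + tn + fn,
           sensitivity = tp + fn,
           specificity = tn + fp)
  num <- c(accuracy = tp + tn, sensitivity = tp, specificity = tn)
  out <- ifelse(den > 0, 100 * num / den, NaN)
  if (!is.na(digits)) out <- .roundHalfUp(out, digits)
  names(out) <- names(den)
  undef <- names(den)[den == 0]
  if (length(undef)) {
    warning("undefined metric(s) (zero denominator): ",
            paste(undef, collapse = ", "))
    attr(out, "undefined") <- undef
  }
  out
}

#' ROC curve and AUC of apnea-class scores
#'
#' Sweeps every distinct score as a decision threshold (predict `"A"`
#' when `score >= threshold`), yielding one ROC point per threshold
#' plus the (0,0) endpoint, and integrates the curve with the
#' trapezoidal rule. Equivalent to the normalized Mann-Whitney U
#' statistic.
#'
#' @param scores numeric apnea-class scores (e.g. softmax
#'   probabilities).
#' @param labels character `"N"`/`"A"` vector; both classes must be
#'   present.
#' @return A list: `roc`, a data.frame with columns `threshold`, `fpr`,
#'   `tpr` (threshold `Inf` for the (0,0) point), and `auc` in
#'   `[0, 1]`.
#' @examples
#' rocAuc(c(.9, .8, .3, .2), c("A", "A", "N", "N"))$auc  # 1
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  y <- labels == "A"
  if (!any(y) || all(y))
    stop("ROC requires both classes in `labels`")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  nPos <- sum(y)
  nNeg <- sum(!y)
  ## cumulative counts at each distinct threshold (>= threshold rule)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(yy)[last]
  fp <- cumsum(!yy)[last]
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / nNeg),
                    tpr = c(0, tp / nPos))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate a model on a segment set
#'
#' Convenience wrapper: predicts, then reports the confusion matrix,
#' percent metrics and ROC/AUC.
#'
#' @param model an [ApneaCNN-class].
#' @param segments a [MinuteSegmentSet-class].
#' @return A list: `probs`, `predictions`, `confusion`
#'   ([ConfusionMatrix-class]), `metrics` (percent), `auc`, `roc`.
#' @export
evaluateModel <- function(model, segments) {
  probs <- predictSegments(model, segments)
  pred <- predictLabels(model, probs = probs)
  labels <- segmentLabels(segments)
  cm <- confusionCounts(labels, pred)
  ## ROC needs both classes; a single-class subset (e.g. one non-OSA
  ## recording) still gets counts and metrics, with AUC undefined
  if (length(unique(labels)) == 2L) {
    ra <- rocAuc(probs[, "A"], labels)
  } else {
    warning("labels contain a single class; AUC is undefined")
    ra <- list(auc = NA_real_, roc = NULL)
  }
  list(probs = probs, predictions = pred, confusion = cm,
       metrics = classificationMetrics(cm), auc = ra$auc, roc = ra$roc)
}

#' Write an evaluation report to disk
#'
#' Emits `metrics.json` (counts, percent metrics, AUC) and
#' `roc.csv` (the ROC points) under `outDir`.
#'
#' @param evaluation a list from [evaluateModel()].
#' @param outDir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
exportEvaluation <- function(evaluation, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cm <- evaluation$confusion
  js <- list(confusion = list(TP = cm@TP, FP = cm@FP, TN = cm@TN,
                              FN = cm@FN),
             metrics = as.list(evaluation$metrics),
             auc = evaluation$auc)
  metricsPath <- file.path(outDir, "metrics.json")
  jsonlite::write_json(js, metricsPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(metrics = metricsPath)
  if (!is.null(evaluation$roc)) {
    rocPath <- file.path(outDir, "roc.csv")
    utils::write.csv(evaluation$roc, rocPath, row.names = FALSE)
    paths <- c(paths, roc = rocPath)
  }
  invisible(paths)
}
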