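## Per-recording OSA screening. The apnea-hypopnea index of a
## recording is estimated from per-minute predictions as
##   AHI = 60 * N / L
## with L the number of 1-minute segments and N the number predicted
## apneic; a recording with AHI >= 5 events/hour (inclusive, the AASM
## cutoff) is called OSA.

#' Estimate the AHI from per-minute detections
#'
#' `AHI = 60 * nApnea / L` events per hour.
#'
#' @param L number of 1-minute segments in the recording, `>= 1`.
#' @param nApnea number of minutes detected as apnea, in `[0, L]`.
#' @return Estimated AHI in events/hour.
#' @examples
#' estimateAhi(480, 40)  # 5
#' @export
estimateAhi <- function(L, nApnea) {
  if (any(L < 1)) stop("L must be >= 1")
  if (any(nApnea < 0 | nApnea > L))
    stop("nApnea must lie in [0, L]")
  60 * nApnea / L
}

#' OSA call from an estimated AHI
#'
#' `"OSA"` when `ahi >= threshold` (inclusive; the AASM definition is
#' an AHI of five or greater), else `"non-OSA"`.
#'
#' @param ahi estimated AHI, events/hour, `>= 0` (vectorized).
#' @param threshold diagnostic cutoff, events/hour.
#' @return Character vector of `"OSA"` / `"non-OSA"`.
#' @examples
#' classifyRecording(c(4.999, 5))  # "non-OSA" "OSA"
#' @export
classifyRecording <- function(ahi, threshold = 5) {
  if (any(ahi < 0)) stop("ahi must be non-negative")
  ifelse(ahi >= threshold, "OSA", "non-OSA")
}

#' Per-recording diagnoses from per-minute predictions
#'
#' Aggregates predicted labels by recording into the diagnosis table.
#'
#' @param recordIds character vector, source recording of each minute.
#' @param predictions character `"N"`/`"A"` per-minute predictions.
#' @param threshold OSA cutoff in events/hour.
#' @return A data.frame with one row per recording: `recordId`, `L`,
#'   `nApnea`, `estimatedAhi`, `call`.
#' @export
diagnoseRecordings <- function(recordIds, predictions, threshold = 5) {
  if (length(recordIds) != length(predictions))
    stop("recordIds and predictions must have equal length")
  ids <- unique(recordIds)
  L <- as.integer(table(factor(recordIds, levels = ids)))
  nA <- as.integer(tapply(predictions == "A",
                          factor(recordIds, levels = ids), sum))
  ahi <- estimateAhi(L, nA)
  data.frame(recordId = ids, L = L, nApnea = nA, estimatedAhi = ahi,
             call = classifyRecording(ahi, threshold),
             stringsAsFactors = FALSE)
}

#' Cohort-level screening performance
#'
#' Joins per-recording diagnoses against the truth table and reports
#' recording-level accuracy / sensitivity / specificity (OSA =
#' positive class, percent, one decimal) plus two Pearson correlations
#' of the estimated AHI: against the reference AHI (e.g. the
#' polysomnography value shipped with a database) and, when per-minute
#' annotations are available, against the annotation-derived AHI
#' `60 * nAnnotatedApnea / L`. The two are distinct quantities and are
#' reported separately.
#'
#' @param diagnoses data.frame from [diagnoseRecordings()].
#' @param truth data.frame with columns `recordId`, `osa` (`"OSA"` /
#'   `"non-OSA"` or logical), and optionally `referenceAhi` and
#'   `annotationAhi`.
#' @return A list: `table` (merged per-recording report), `confusion`
#'   ([ConfusionMatrix-class] over recordings), `metrics` (percent),
#'   `corReference`, `corAnnotation` (Pearson r or `NA`).
#' @export
cohortSummary <- function(diagnoses, truth) {
  if (!setequal(diagnoses$recordId, truth$recordId))
    stop("record ids in diagnoses and truth do not match")
  truth <- truth[match(diagnoses$recordId, truth$recordId), ]
  osa <- truth$osa
  if (is.logical(osa)) osa <- ifelse(osa, "OSA", "non-OSA")

  ## recording-level counts, OSA positive
  cm <- confusionMatrix(
    TP = sum(osa == "OSA" & diagnoses$call == "OSA"),
    FP = sum(osa == "non-OSA" & diagnoses$call == "OSA"),
    TN = sum(osa == "non-OSA" & diagnoses$call == "non-OSA"),
    FN = sum(osa == "OSA" & diagnoses$call == "non-OSA"))

  ## Pearson r is undefined for a constant vector on either side
  safeCor <- function(x, y) {
    if (is.null(y) || stats::sd(y) == 0 || stats::sd(x) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  corReference <- safeCor(diagnoses$estimatedAhi, truth$referenceAhi)
  corAnnotation <- safeCor(diagnoses$estimatedAhi, truth$annotationAhi)

  tab <- cbind(diagnoses,
               truth[, setdiff(names(truth), "recordId"), drop = FALSE])
  list(table = tab, confusion = cm,
       metrics = classificationMetrics(cm),
       corReference = corReference, corAnnotation = corAnnotation)
}

#' Write a cohort report CSV
#'
#' @param summary list from [cohortSummary()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportCohortReport <- function(summary, path) {
  utils::write.csv(summary$table, path, row.names = FALSE)
  invisible(path)
}
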