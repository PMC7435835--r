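#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: `recordId`
#' (record identifier(s)), `sampleRate` (Hz), `signalValues` (raw
#' amplitude vector), `minuteLabels` (per-minute `"N"`/`"A"`
#' annotations), `referenceAhi` (reference AHI, events/hour),
#' `nMinutes` (whole minutes in a recording), `nSegments`,
#' `segmentMatrix` and `segmentLabels` (segment container contents).
#'
#' @param object an [ECGRecording-class] or [MinuteSegmentSet-class].
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("minuteLabels", function(object) standardGeneric("minuteLabels"))
#' @rdname accessors
#' @export
setGeneric("referenceAhi", function(object) standardGeneric("referenceAhi"))
#' @rdname accessors
#' @export
setGeneric("nMinutes", function(object) standardGeneric("nMinutes"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("segmentMatrix", function(object) standardGeneric("segmentMatrix"))
#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @rdname accessors
setMethod("recordId", "ECGRecording", function(object) object@recordId)
#' @rdname accessors
setMethod("sampleRate", "ECGRecording", function(object) object@fs)
#' @rdname accessors
setMethod("signalValues", "ECGRecording", function(object) object@signal)
#' @rdname accessors
setMethod("minuteLabels", "ECGRecording", function(object) object@minuteLabels)
#' @rdname accessors
setMethod("referenceAhi", "ECGRecording", function(object) object@referenceAhi)
#' @rdname accessors
setMethod("nMinutes", "ECGRecording", function(object) length(object@minuteLabels))

#' @rdname accessors
setMethod("recordId", "MinuteSegmentSet", function(object) object@recordId)
#' @rdname accessors
setMethod("nSegments", "MinuteSegmentSet", function(object) nrow(object@segments))
#' @rdname accessors
setMethod("segmentMatrix", "MinuteSegmentSet", function(object) object@segments)
#' @rdname accessors
setMethod("segmentLabels", "MinuteSegmentSet", function(object) object@labels)

setMethod("show", "ECGRecording", function(object) {
  cat(sprintf("ECGRecording '%s': %.0f Hz, %d samples, %d minutes (%d A / %d N)",
              object@recordId, object@fs, length(object@signal),
              length(object@minuteLabels),
              sum(object@minuteLabels == "A"),
              sum(object@minuteLabels == "N")))
  if (!is.na(object@referenceAhi))
    cat(sprintf(", reference AHI %.1f/h", object@referenceAhi))
  cat("\n")
})

setMethod("show", "MinuteSegmentSet", function(object) {
  cat(sprintf("MinuteSegmentSet: %d segments x %d samples from %d record(s) (%d A / %d N)\n",
              nrow(object@segments), ncol(object@segments),
              length(unique(object@recordId)),
              sum(object@labels == "A"), sum(object@labels == "N")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %d feature layer(s) [conv %d x %d -> BN -> ReLU -> pool %d/%d -> dropout %.2f],\n  %d classification layer(s) [FC-%d], %d outputs, input length %d\n  parameters: %s total (%s trainable)\n",
    object@nFeatureLayers, object@nFilters, object@kernelSize,
    object@poolSize, object@poolStride, object@dropoutRate,
    object@nClassLayers, object@fcUnits, object@nOutputs,
    object@inputLength,
    format(countParameters(object), big.mark = ","),
    format(countParameters(object, trainableOnly = TRUE), big.mark = ",")))
})

setMethod("show", "ApneaCNN", function(object) {
  cat(sprintf("ApneaCNN model (seed %d)\n", object@seed))
  show(object@config)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (A positive): TP=%d FP=%d TN=%d FN=%d\n",
              object@TP, object@FP, object@TN, object@FN))
  m <- classificationMetrics(object)
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
})
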