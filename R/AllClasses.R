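#' @import methods
NULL

## Labels used throughout: "N" = normal minute, "A" = apnea minute.
.APNEA_ALPHABET <- c("N", "A")

#' ECGRecording: a single-lead ECG with per-minute apnea annotations
#'
#' Container for one continuous single-lead ECG recording sampled at a
#' fixed rate (100 Hz for the Apnea-ECG conventions this package
#' follows) together with one annotation symbol per minute: `"N"`
#' (normal breathing) or `"A"` (apnea/hypopnea present in that
#' minute). Label `i` (1-based) covers the half-open sample window
#' `[(i-1)*60*fs, i*60*fs)`; a trailing partial minute of signal is
#' discarded at construction.
#'
#' @slot recordId single string identifying the recording.
#' @slot fs sampling rate in Hz.
#' @slot signal numeric vector of amplitudes (mV for real recordings;
#'   arbitrary units for synthetic data).
#' @slot minuteLabels character vector over minutes, values in
#'   `c("N", "A")`.
#' @slot referenceAhi reference apnea-hypopnea index in events/hour
#'   (e.g. the polysomnography value shipped with a database), or
#'   `NA_real_` when unknown.
#'
#' @aliases ECGRecording-class
#' @exportClass ECGRecording
setClass("ECGRecording",
  representation(
    recordId = "character",
    fs = "numeric",
    signal = "numeric",
    minuteLabels = "character",
    referenceAhi = "numeric"
  ),
  prototype(referenceAhi = NA_real_)
)

setValidity("ECGRecording", function(object) {
  msg <- character()
  if (length(object@recordId) != 1L || is.na(object@recordId) ||
      !nzchar(object@recordId))
    msg <- c(msg, "recordId must be a single non-empty string")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  bad <- setdiff(unique(object@minuteLabels), .APNEA_ALPHABET)
  if (length(bad))
    msg <- c(msg, sprintf("minute labels outside {N, A}: %s",
                          paste(bad, collapse = ", ")))
  expected <- floor(length(object@signal) / (60 * object@fs))
  if (length(object@minuteLabels) != expected)
    msg <- c(msg, sprintf(
      "length(minuteLabels) is %d but floor(length(signal)/(60*fs)) is %d",
      length(object@minuteLabels), expected))
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecording
#'
#' Trailing signal samples beyond the last whole minute are dropped.
#' If the number of labels and the number of whole minutes of signal
#' disagree, both are truncated to the shorter with a warning (source
#' databases occasionally disagree by one minute at the end of a
#' recording).
#'
#' @param recordId single string.
#' @param fs sampling rate in Hz (100 for Apnea-ECG-style data).
#' @param signal numeric amplitude vector.
#' @param minuteLabels character vector of `"N"`/`"A"`, one per minute.
#' @param referenceAhi optional reference AHI in events/hour.
#' @return An [ECGRecording-class] object.
#' @examples
#' rec <- ECGRecording("demo", 100, rnorm(100 * 60 * 2), c("N", "A"))
#' nMinutes(rec)
#' @export
ECGRecording <- function(recordId, fs, signal, minuteLabels,
                         referenceAhi = NA_real_) {
  fs <- as.numeric(fs)
  signal <- as.numeric(signal)
  minuteLabels <- as.character(minuteLabels)
  spm <- 60 * fs
  nmin <- floor(length(signal) / spm)
  if (length(minuteLabels) != nmin) {
    n <- min(length(minuteLabels), nmin)
    warning(sprintf(
      "record %s: %d annotation(s) but %d whole minute(s) of signal; truncating to %d",
      recordId, length(minuteLabels), nmin, n))
    minuteLabels <- minuteLabels[seq_len(n)]
    nmin <- n
  }
  signal <- signal[seq_len(nmin * spm)]
  new("ECGRecording", recordId = as.character(recordId), fs = fs,
      signal = signal, minuteLabels = minuteLabels,
      referenceAhi = as.numeric(referenceAhi))
}

#' MinuteSegmentSet: preprocessed 1-minute ECG segments
#'
#' A set of fixed-length, preprocessed (bandpass-filtered and z-score
#' standardized) 1-minute ECG segments with their annotation labels
#' and provenance. Segments are rows of a numeric matrix; at 100 Hz a
#' segment has 6000 samples.
#'
#' @slot segments numeric matrix, one row per 1-minute segment.
#' @slot labels character vector (`"N"`/`"A"`), one per row.
#' @slot recordId character vector, source recording of each row.
#' @slot minuteIndex integer vector, 0-based minute index of each row
#'   within its source recording.
#'
#' @aliases MinuteSegmentSet-class
#' @exportClass MinuteSegmentSet
setClass("MinuteSegmentSet",
  representation(
    segments = "matrix",
    labels = "character",
    recordId = "character",
    minuteIndex = "integer"
  )
)

setValidity("MinuteSegmentSet", function(object) {
  n <- nrow(object@segments)
  msg <- character()
  if (length(object@labels) != n || length(object@recordId) != n ||
      length(object@minuteIndex) != n)
    msg <- c(msg, "labels, recordId and minuteIndex must have one entry per segment row")
  bad <- setdiff(unique(object@labels), .APNEA_ALPHABET)
  if (length(bad))
    msg <- c(msg, sprintf("labels outside {N, A}: %s", paste(bad, collapse = ", ")))
  if (any(object@minuteIndex < 0L))
    msg <- c(msg, "minuteIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MinuteSegmentSet
#'
#' @param segments numeric matrix, one 1-minute segment per row.
#' @param labels character `"N"`/`"A"` labels, one per row.
#' @param recordId source record id(s), recycled to one per row.
#' @param minuteIndex 0-based minute indices; defaults to
#'   `0:(nrow(segments)-1)`.
#' @return A [MinuteSegmentSet-class].
#' @export
MinuteSegmentSet <- function(segments, labels, recordId = "segset",
                             minuteIndex = NULL) {
  segments <- as.matrix(segments)
  n <- nrow(segments)
  if (is.null(minuteIndex)) minuteIndex <- seq_len(n) - 1L
  new("MinuteSegmentSet", segments = segments,
      labels = as.character(labels),
      recordId = rep_len(as.character(recordId), n),
      minuteIndex = as.integer(minuteIndex))
}

#' ModelConfig: architecture description of the 1D CNN
#'
#' Describes the apnea-detection network: `nFeatureLayers` identical
#' feature-extraction blocks (1D convolution with `nFilters` filters of
#' width `kernelSize`, 'same' padding -> batch normalization -> ReLU ->
#' max pooling (`poolSize`, stride `poolStride`) -> dropout), a flatten
#' layer, `nClassLayers` identical classification blocks (fully
#' connected `fcUnits` -> batch normalization -> ReLU -> dropout), and a
#' final `nOutputs`-unit softmax layer. The reference architecture uses
#' 10 feature layers, 45 filters of width 32, 4 FC-512 classification
#' layers and 2 outputs on 6000-sample inputs.
#'
#' @slot nFeatureLayers integer, number of feature-extraction blocks.
#' @slot nFilters filters per convolution.
#' @slot kernelSize convolution kernel width in samples.
#' @slot poolSize,poolStride max-pooling window and stride.
#' @slot dropoutRate dropout probability during training.
#' @slot nClassLayers number of FC classification blocks.
#' @slot fcUnits units per classification block.
#' @slot nOutputs output classes (2: N vs A).
#' @slot inputLength samples per input segment (6000 at 100 Hz).
#' @slot bnMomentum,bnEpsilon batch-normalization moving-average
#'   momentum and variance epsilon (Keras-era conventions 0.99, 1e-3).
#'
#' @aliases ModelConfig-class
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    nFeatureLayers = "integer",
    nFilters = "integer",
    kernelSize = "integer",
    poolSize = "integer",
    poolStride = "integer",
    dropoutRate = "numeric",
    nClassLayers = "integer",
    fcUnits = "integer",
    nOutputs = "integer",
    inputLength = "integer",
    bnMomentum = "numeric",
    bnEpsilon = "numeric"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nFeatureLayers < 0L || object@nFeatureLayers > 12L)
    msg <- c(msg, "nFeatureLayers must be in [0, 12]")
  if (object@nFeatureLayers > 0L &&
      object@inputLength < 2^object@nFeatureLayers)
    msg <- c(msg, "inputLength must be >= 2^nFeatureLayers (non-empty feature maps)")
  if (object@nFilters < 1L) msg <- c(msg, "nFilters must be >= 1")
  if (object@kernelSize < 1L) msg <- c(msg, "kernelSize must be >= 1")
  if (object@poolSize != 2L || object@poolStride != 2L)
    msg <- c(msg, "only pool size 2 with stride 2 is supported")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@nClassLayers < 0L) msg <- c(msg, "nClassLayers must be >= 0")
  if (object@nOutputs < 2L) msg <- c(msg, "nOutputs must be >= 2")
  if (object@inputLength < 1L) msg <- c(msg, "inputLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a ModelConfig
#'
#' Defaults reproduce the reference 10-layer architecture (45 filters,
#' kernel 32, pool 2/2, dropout 0.5, four FC-512 classification layers,
#' 2 softmax outputs, 6000-sample input).
#'
#' @param nFeatureLayers number of feature-extraction blocks (0-12).
#' @param nFilters,kernelSize convolution filters and kernel width.
#' @param poolSize,poolStride max-pooling window and stride (2/2).
#' @param dropoutRate dropout probability in `[0, 1)`.
#' @param nClassLayers,fcUnits classification blocks and their width.
#' @param nOutputs number of classes.
#' @param inputLength samples per segment.
#' @param bnMomentum,bnEpsilon batch-normalization constants.
#' @return A [ModelConfig-class].
#' @examples
#' cfg <- modelConfig()            # the reference 10-layer network
#' countParameters(cfg)            # 1499788, i.e. ~1.5 million
#' @export
modelConfig <- function(nFeatureLayers = 10, nFilters = 45,
                        kernelSize = 32, poolSize = 2, poolStride = 2,
                        dropoutRate = 0.5, nClassLayers = 4,
                        fcUnits = 512, nOutputs = 2, inputLength = 6000,
                        bnMomentum = 0.99, bnEpsilon = 1e-3) {
  new("ModelConfig",
      nFeatureLayers = as.integer(nFeatureLayers),
      nFilters = as.integer(nFilters),
      kernelSize = as.integer(kernelSize),
      poolSize = as.integer(poolSize),
      poolStride = as.integer(poolStride),
      dropoutRate = as.numeric(dropoutRate),
      nClassLayers = as.integer(nClassLayers),
      fcUnits = as.integer(fcUnits),
      nOutputs = as.integer(nOutputs),
      inputLength = as.integer(inputLength),
      bnMomentum = as.numeric(bnMomentum),
      bnEpsilon = as.numeric(bnEpsilon))
}

#' ApneaCNN: a trainable 1D CNN model instance
#'
#' Holds the architecture configuration, all weight tensors (including
#' batch-normalization moving statistics) and the seed the weights were
#' initialized from. Created by [buildModel()].
#'
#' @slot config the [ModelConfig-class].
#' @slot weights nested list of parameter matrices/vectors.
#' @slot seed integer seed used for He-normal initialization.
#'
#' @aliases ApneaCNN-class
#' @exportClass ApneaCNN
setClass("ApneaCNN",
  representation(
    config = "ModelConfig",
    weights = "list",
    seed = "integer"
  )
)

#' ConfusionMatrix: per-minute detection counts
#'
#' Apnea (`"A"`) is the positive class: `TP` apnea minutes called
#' apnea, `FN` apnea minutes called normal, `TN` normal called normal,
#' `FP` normal called apnea.
#'
#' @slot TP,FP,TN,FN non-negative integer counts.
#' @aliases ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(TP = "integer", FP = "integer",
                 TN = "integer", FN = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (length(v) != 4L || anyNA(v) || any(v < 0L))
    "TP, FP, TN, FN must be single non-negative integers"
  else TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param TP,FP,TN,FN non-negative counts (apnea = positive class).
#' @return A [ConfusionMatrix-class].
#' @examples
#' classificationMetrics(confusionMatrix(TP = 5287, FP = 854,
#'                                       TN = 9863, FN = 1230))
#' @export
confusionMatrix <- function(TP, FP, TN, FN) {
  new("ConfusionMatrix", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN))
}

#' TrainingConfig: the training protocol
#'
#' Mini-batch Adam on categorical cross-entropy with best-validation
#' checkpointing, repeated over independent experiments. Reference
#' protocol: batch size 10, 50 epochs, 10 experiments.
#'
#' @slot batchSize mini-batch size.
#' @slot epochs training epochs per experiment.
#' @slot learningRate,beta1,beta2,epsilon Adam hyperparameters.
#' @slot nExperiments number of repeated experiments.
#' @slot seeds integer vector, one seed per experiment.
#'
#' @aliases TrainingConfig-class
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    batchSize = "integer",
    epochs = "integer",
    learningRate = "numeric",
    beta1 = "numeric",
    beta2 = "numeric",
    epsilon = "numeric",
    nExperiments = "integer",
    seeds = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@nExperiments < 1L) msg <- c(msg, "nExperiments must be >= 1")
  if (length(object@seeds) != object@nExperiments)
    msg <- c(msg, "length(seeds) must equal nExperiments")
  if (length(msg)) msg else TRUE
})

#' Create a TrainingConfig
#'
#' @param batchSize mini-batch size (reference protocol: 10).
#' @param epochs epochs per experiment (reference protocol: 50).
#' @param learningRate,beta1,beta2,epsilon Adam hyperparameters
#'   (defaults 1e-3, 0.9, 0.999, 1e-7).
#' @param nExperiments number of repeated experiments.
#' @param seeds integer seeds, one per experiment; defaults to
#'   `seq_len(nExperiments)`.
#' @return A [TrainingConfig-class].
#' @export
trainingConfig <- function(batchSize = 10, epochs = 50,
                           learningRate = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, epsilon = 1e-7,
                           nExperiments = 10, seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(nExperiments)
  new("TrainingConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), learningRate = as.numeric(learningRate),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      epsilon = as.numeric(epsilon),
      nExperiments = as.integer(nExperiments), seeds = as.integer(seeds))
}

#' SyntheticConfig: parameters of the synthetic ECG cohort generator
#'
#' See [generateCohort()] for the generative model.
#'
#' @slot nRecords,minutesPerRecord cohort dimensions.
#' @slot fs sampling rate in Hz.
#' @slot baseHr resting heart rate, beats/min.
#' @slot hrSwing peak-to-peak cyclic heart-rate swing of apnea minutes,
#'   beats/min.
#' @slot periodS apnea brady-tachycardia cycle length, seconds
#'   (constrained to 25-100 s).
#' @slot wanderFreq,wanderAmp baseline-wander frequency (Hz, < 0.5) and
#'   amplitude (mV).
#' @slot noiseSd additive Gaussian noise, mV.
#' @slot apneaFraction target overall fraction of minutes labelled A.
#' @slot osaFraction fraction of records that are OSA-like.
#' @slot ampModDepth EDR-like amplitude-modulation depth on apnea
#'   minutes.
#' @slot seed integer generator seed.
#'
#' @aliases SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nRecords = "integer",
    minutesPerRecord = "integer",
    fs = "numeric",
    baseHr = "numeric",
    hrSwing = "numeric",
    periodS = "numeric",
    wanderFreq = "numeric",
    wanderAmp = "numeric",
    noiseSd = "numeric",
    apneaFraction = "numeric",
    osaFraction = "numeric",
    ampModDepth = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@apneaFraction < 0 || object@apneaFraction > 1)
    msg <- c(msg, "apneaFraction must be in [0, 1]")
  if (object@periodS < 25 || object@periodS > 100)
    msg <- c(msg, "periodS must lie in [25, 100] seconds")
  if (object@wanderFreq >= 0.5 || object@wanderFreq <= 0)
    msg <- c(msg, "wanderFreq must lie in (0, 0.5) Hz")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a SyntheticConfig
#'
#' Defaults describe the package's standard desk-scale cohort: 8
#' records of 60 minutes at 100 Hz, 5 of 8 records OSA-like, an overall
#' apnea-minute prevalence near 0.35 (the released Apnea-ECG set has
#' prevalence 0.39), 20 bpm peak-to-peak cyclic heart-rate swings with
#' a 50 s period on apnea minutes, 0.2 Hz baseline wander and mild
#' additive noise.
#'
#' @param nRecords,minutesPerRecord cohort dimensions.
#' @param fs sampling rate in Hz.
#' @param baseHr resting heart rate, beats/min.
#' @param hrSwing peak-to-peak apnea heart-rate swing, beats/min.
#' @param periodS apnea cycle period in seconds (25-100).
#' @param wanderFreq,wanderAmp baseline wander frequency (Hz) and
#'   amplitude (mV).
#' @param noiseSd additive noise standard deviation (mV).
#' @param apneaFraction target overall apnea-minute fraction.
#' @param osaFraction fraction of OSA-like records.
#' @param ampModDepth EDR-like amplitude modulation depth for apnea
#'   minutes.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nRecords = 8, minutesPerRecord = 60,
                            fs = 100, baseHr = 72, hrSwing = 20,
                            periodS = 50, wanderFreq = 0.2,
                            wanderAmp = 0.4, noiseSd = 0.03,
                            apneaFraction = 0.35, osaFraction = 0.625,
                            ampModDepth = 0.15, seed = 20201) {
  new("SyntheticConfig", nRecords = as.integer(nRecords),
      minutesPerRecord = as.integer(minutesPerRecord), fs = as.numeric(fs),
      baseHr = as.numeric(baseHr), hrSwing = as.numeric(hrSwing),
      periodS = as.numeric(periodS), wanderFreq = as.numeric(wanderFreq),
      wanderAmp = as.numeric(wanderAmp), noiseSd = as.numeric(noiseSd),
      apneaFraction = as.numeric(apneaFraction),
      osaFraction = as.numeric(osaFraction),
      ampModDepth = as.numeric(ampModDepth), seed = as.integer(seed))
}
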