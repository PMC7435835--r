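## Synthetic single-lead ECG generator with planted per-minute apnea
## labels.
##
## Each minute is a quasi-periodic train of Gaussian-shaped QRS
## surrogates placed by integrating an instantaneous heart-rate
## profile, plus sinusoidal baseline wander (below 0.5 Hz) and white
## Gaussian noise. Apnea minutes carry the cyclic bradycardia-
## tachycardia oscillation that ECG-based apnea detectors exploit (a
## configurable peak-to-peak heart-rate swing with a 25-100 s period)
## and an EDR-like amplitude modulation at the same period; normal
## minutes carry only mild respiratory-band heart-rate jitter. The
## generator is fully deterministic given its seed.

#' Generate one synthetic 1-minute ECG segment
#'
#' @param label `"N"` or `"A"`: whether the minute carries the cyclic
#'   apnea heart-rate signature.
#' @param fs sampling rate in Hz.
#' @param baseHr mean heart rate, beats/min.
#' @param hrSwing peak-to-peak heart-rate swing of apnea minutes,
#'   beats/min.
#' @param periodS apnea modulation period, seconds.
#' @param wanderFreq,wanderAmp baseline-wander frequency (Hz) and
#'   amplitude (mV); set `wanderAmp = 0` to disable.
#' @param noiseSd additive Gaussian noise sd (mV); 0 to disable.
#' @param ampModDepth relative amplitude-modulation depth applied to
#'   apnea minutes.
#' @param phase starting phase of the modulation cycle, radians.
#' @return Numeric vector of `60 * fs` samples (mV). Consumes the R
#'   RNG stream; seed outside for determinism.
#' @export
generateBeatTrain <- function(label = "N", fs = 100, baseHr = 72,
                              hrSwing = 20, periodS = 50,
                              wanderFreq = 0.2, wanderAmp = 0.4,
                              noiseSd = 0.03, ampModDepth = 0.15,
                              phase = stats::runif(1, 0, 2 * pi)) {
  stopifnot(label %in% .APNEA_ALPHABET, fs > 0)
  nSamples <- as.integer(60 * fs)
  t <- (seq_len(nSamples) - 1L) / fs

  if (label == "A") {
    hr <- baseHr + (hrSwing / 2) * sin(2 * pi * t / periodS + phase)
    amp <- 1 + ampModDepth * sin(2 * pi * t / periodS + phase + pi / 3)
  } else {
    ## mild respiratory sinus arrhythmia around 0.25 Hz, ~3 bpm swing
    hr <- baseHr + 1.5 * sin(2 * pi * 0.25 * t + phase) +
      stats::rnorm(1, 0, 1)
    amp <- rep(1, nSamples)
  }

  ## integrate instantaneous rate; a beat fires at each whole cycle
  phase0 <- stats::runif(1)
  cycles <- phase0 + cumsum(hr / 60) / fs
  beatIdx <- which(diff(floor(c(phase0, cycles))) >= 1)

  x <- numeric(nSamples)
  width <- 0.012 * fs                       # QRS surrogate sd, ~12 ms
  halfSupport <- ceiling(4 * width)
  kernelOffsets <- -halfSupport:halfSupport
  kernel <- exp(-0.5 * (kernelOffsets / width)^2)
  for (b in beatIdx) {
    a <- amp[b] * (1 + stats::rnorm(1, 0, 0.03))
    pos <- b + kernelOffsets
    ok <- pos >= 1L & pos <= nSamples
    x[pos[ok]] <- x[pos[ok]] + a * kernel[ok]
  }

  if (wanderAmp > 0)
    x <- x + wanderAmp * sin(2 * pi * wanderFreq * t +
                               stats::runif(1, 0, 2 * pi))
  if (noiseSd > 0)
    x <- x + stats::rnorm(nSamples, 0, noiseSd)
  x
}

#' Generate a labelled synthetic cohort
#'
#' Draws `nRecords` recordings of `minutesPerRecord` minutes.
#' A fraction `osaFraction` of the records (rounded, at least one of
#' each class when possible) are OSA-like: their minutes are labelled
#' `"A"` independently with probability
#' `apneaFraction / osaFraction` (so the cohort-wide apnea prevalence
#' matches `apneaFraction` in expectation); the remaining records are
#' non-OSA-like with apnea probability 0.01. Each recording's
#' reference AHI is computed from its planted labels via
#' `60 * nApnea / L`, so planted truth and annotation-derived AHI
#' coincide by construction.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return A list: `records` (list of [ECGRecording-class]) and
#'   `truth` (data.frame: `recordId`, `osa`, `referenceAhi`,
#'   `annotationAhi`, `nApnea`, `L`).
#' @examples
#' co <- generateCohort(syntheticConfig(nRecords = 2,
#'                                      minutesPerRecord = 3))
#' co$truth
#' @export
generateCohort <- function(cfg = syntheticConfig()) {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nRecords
  nOsa <- round(cfg@osaFraction * n)
  if (cfg@osaFraction > 0 && nOsa == 0L) nOsa <- 1L
  if (cfg@osaFraction < 1 && nOsa == n) nOsa <- n - 1L
  isOsa <- seq_len(n) <= nOsa
  pApnea <- ifelse(isOsa,
                   min(1, cfg@apneaFraction / max(cfg@osaFraction, 1e-9)),
                   0.01)
  if (cfg@apneaFraction == 0) pApnea[] <- 0

  spm <- as.integer(60 * cfg@fs)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn%02d", i)
    labels <- ifelse(stats::runif(cfg@minutesPerRecord) < pApnea[i],
                     "A", "N")
    sig <- numeric(cfg@minutesPerRecord * spm)
    for (m in seq_len(cfg@minutesPerRecord))
      sig[((m - 1L) * spm + 1L):(m * spm)] <- generateBeatTrain(
        labels[m], fs = cfg@fs, baseHr = cfg@baseHr,
        hrSwing = cfg@hrSwing, periodS = cfg@periodS,
        wanderFreq = cfg@wanderFreq, wanderAmp = cfg@wanderAmp,
        noiseSd = cfg@noiseSd, ampModDepth = cfg@ampModDepth)
    ahi <- estimateAhi(length(labels), sum(labels == "A"))
    records[[i]] <- ECGRecording(id, cfg@fs, sig, labels,
                                 referenceAhi = ahi)
    truth[[i]] <- data.frame(
      recordId = id, osa = classifyRecording(ahi),
      referenceAhi = ahi, annotationAhi = ahi,
      nApnea = sum(labels == "A"), L = length(labels),
      stringsAsFactors = FALSE)
  }
  names(records) <- vapply(records, recordId, character(1))
  list(records = records, truth = do.call(rbind, truth))
}

#' Hold out whole recordings from a cohort
#'
#' Record-wise split (the evaluation convention for recording-level
#' data: minutes of one recording never straddle the split).
#'
#' @param cohort list from [generateCohort()].
#' @param heldOut record ids (or indices) to hold out.
#' @return A list of two record lists, `train` and `heldout`.
#' @export
splitCohort <- function(cohort, heldOut) {
  recs <- cohort$records
  if (is.numeric(heldOut)) heldOut <- names(recs)[heldOut]
  stopifnot(all(heldOut %in% names(recs)),
            length(heldOut) < length(recs))
  list(train = recs[setdiff(names(recs), heldOut)],
       heldout = recs[heldOut])
}
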