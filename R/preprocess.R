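## Per-minute signal conditioning.
##
## Each 1-minute segment is passed through a 4-pole digital Butterworth
## bandpass (0.5-15 Hz at 100 Hz sampling by default) to remove
## baseline wander and high-frequency interference, then z-score
## standardized to zero mean and unit standard deviation. At the
## default settings the filter's difference equation is
##   y(n) = 0.1242 x(n) - 0.2483 x(n-2) + 0.1242 x(n-4)
##        + 2.7422 y(n-1) - 2.7907 y(n-2) + 1.3311 y(n-3) - 0.2831 y(n-4).

#' Design the Butterworth bandpass filter
#'
#' Designs a 4-pole (degree-4 denominator) digital Butterworth bandpass
#' filter via the bilinear transform, i.e. an order-2 Butterworth
#' prototype applied as a bandpass, using [signal::butter()]. At the
#' reference settings (100 Hz sampling, 0.5-15 Hz passband) the
#' numerator has the structure `b0 * c(1, 0, -2, 0, 1)` with
#' `b0 = 0.1242` (to 4 decimals). Gain is exactly zero at DC and at the
#' Nyquist frequency.
#'
#' @param fs sampling rate in Hz.
#' @param low,high passband edges in Hz, `0 < low < high < fs/2`.
#' @return A list with class `"filterCoefficients"`: `b` (feedforward,
#'   length 5), `a` (feedback, length 5, `a[1] == 1`), `fs`, `passband`.
#' @examples
#' co <- designBandpass(100, 0.5, 15)
#' round(co$b[1], 4)    # 0.1242
#' @export
designBandpass <- function(fs = 100, low = 0.5, high = 15) {
  if (!(is.finite(fs) && is.finite(low) && is.finite(high)))
    stop("fs, low and high must be finite numbers")
  if (!(0 < low && low < high && high < fs / 2))
    stop(sprintf(
      "invalid band edges: need 0 < low < high < fs/2, got low=%g high=%g fs=%g",
      low, high, fs))
  bt <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  structure(list(b = as.numeric(bt$b), a = as.numeric(bt$a),
                 fs = fs, passband = c(low, high)),
            class = "filterCoefficients")
}

#' Apply a digital filter as a causal recurrence
#'
#' Runs the direct-form difference equation
#' `y(n) = sum(b[k] x(n-k)) - sum(a[k] y(n-k))` with zero initial
#' conditions (via [signal::filter()]); the output has the same length
#' as the input. No forward-backward (zero-phase) pass is performed:
#' the recurrence is causal, matching per-minute streaming use.
#'
#' @param x numeric sample vector, `length(x) >= 1`.
#' @param coefficients a filter design from [designBandpass()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
applyFilter <- function(x, coefficients = designBandpass()) {
  stopifnot(inherits(coefficients, "filterCoefficients"),
            length(x) >= 1L)
  as.numeric(signal::filter(coefficients$b, coefficients$a,
                            as.numeric(x)))
}

#' Frequency response magnitude of a filter design
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` from the coefficients.
#'
#' @param coefficients a design from [designBandpass()].
#' @param freqHz frequencies in Hz.
#' @return Numeric vector of gain magnitudes.
#' @export
filterGain <- function(coefficients, freqHz) {
  z <- exp(-1i * 2 * pi * freqHz / coefficients$fs)
  k <- seq_along(coefficients$b) - 1
  H <- vapply(z, function(zz)
    sum(coefficients$b * zz^k) / sum(coefficients$a * zz^k),
    complex(1))
  Mod(H)
}

#' Z-score standardization
#'
#' Returns `(x - mean(x)) / sd(x)` with the population standard
#' deviation (divide by `n`); the standardized segment has mean 0 and
#' population standard deviation 1. A zero-variance (flat-line) input
#' returns all zeros with a warning instead of failing, so one corrupt
#' minute cannot abort a whole-recording run.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @return Standardized numeric vector.
#' @export
zScore <- function(x) {
  if (length(x) < 2L) stop("zScore needs at least 2 samples")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    warning("degenerate (zero-variance) segment standardized to zeros")
    return(rep(0, length(x)))
  }
  (x - mu) / sigma
}

#' Preprocess a recording into standardized 1-minute segments
#'
#' Splits the recording into whole minutes (label `i` covering samples
#' `[(i-1)*60*fs, i*60*fs)`), and filters then z-scores each minute
#' independently with zero filter initial conditions, mirroring
#' per-minute acquisition. Preprocessing is stateless across minutes.
#'
#' @param rec an [ECGRecording-class].
#' @param coefficients filter design; defaults to the recording's
#'   sampling rate with the 0.5-15 Hz passband.
#' @return A [MinuteSegmentSet-class] with `nMinutes(rec)` rows of
#'   `60 * sampleRate(rec)` samples each.
#' @export
preprocessRecording <- function(rec, coefficients = NULL) {
  stopifnot(is(rec, "ECGRecording"))
  if (is.null(coefficients))
    coefficients <- designBandpass(sampleRate(rec), 0.5, 15)
  spm <- as.integer(60 * sampleRate(rec))
  n <- nMinutes(rec)
  seg <- matrix(0, nrow = n, ncol = spm)
  for (i in seq_len(n)) {
    x <- rec@signal[((i - 1L) * spm + 1L):(i * spm)]
    y <- applyFilter(x, coefficients)
    seg[i, ] <- withCallingHandlers(
      zScore(y),
      warning = function(w) {
        warning(sprintf("record %s, minute %d: %s",
                        rec@recordId, i - 1L, conditionMessage(w)),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
  }
  MinuteSegmentSet(seg, rec@minuteLabels, rec@recordId,
                   seq_len(n) - 1L)
}

#' Preprocess several recordings and pool their segments
#'
#' @param recs list of [ECGRecording-class] objects.
#' @param coefficients optional shared filter design.
#' @return A pooled [MinuteSegmentSet-class].
#' @export
preprocessCohort <- function(recs, coefficients = NULL) {
  sets <- lapply(recs, preprocessRecording, coefficients = coefficients)
  MinuteSegmentSet(
    do.call(rbind, lapply(sets, segmentMatrix)),
    unlist(lapply(sets, segmentLabels), use.names = FALSE),
    unlist(lapply(sets, recordId), use.names = FALSE),
    unlist(lapply(sets, function(s) s@minuteIndex), use.names = FALSE))
}

#' @export
print.filterCoefficients <- function(x, ...) {
  cat(sprintf("Butterworth bandpass: %g-%g Hz at %g Hz sampling\n",
              x$passband[1], x$passband[2], x$fs))
  cat("  b:", paste(sprintf("%.4f", x$b), collapse = " "), "\n")
  cat("  a:", paste(sprintf("%.4f", x$a), collapse = " "), "\n")
  invisible(x)
}

#' Export filter coefficients as JSON for audit
#'
#' @param coefficients a design from [designBandpass()].
#' @param path optional output file; if `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
filterReport <- function(coefficients, path = NULL) {
  js <- jsonlite::toJSON(unclass(coefficients), digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
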