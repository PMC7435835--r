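# Shared fixtures: everything is generated in code at test time.

# A small architecture that trains in seconds; used wherever the test
# is about mechanics rather than the reference architecture.
tinyModelConfig <- function(...) {
  modelConfig(nFeatureLayers = 1, nFilters = 6, kernelSize = 9,
              nClassLayers = 1, fcUnits = 16, inputLength = 300, ...)
}

# Two easily separable waveform classes at the tiny scale: class "A"
# carries a strong low-frequency amplitude envelope, class "N" is flat
# beat-like noise. Returns a MinuteSegmentSet (segments are z-scored).
tinyToySegments <- function(n, seed, inputLength = 300) {
  set.seed(seed)
  labels <- rep(c("N", "A"), length.out = n)
  t <- seq_len(inputLength) / 100
  segs <- t(vapply(labels, function(lb) {
    base <- sin(2 * pi * 8 * t) + rnorm(inputLength, 0, 0.3)
    if (lb == "A") base <- base * (1 + 0.9 * sin(2 * pi * 0.4 * t))
    zScore(base)
  }, numeric(inputLength)))
  MinuteSegmentSet(segs, labels, "toy")
}

# A short synthetic recording via the generator, deterministic.
smallRecording <- function(minutes = 4, seed = 5, labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(c("N", "A"), length.out = minutes)
  spm <- 6000L
  sig <- numeric(minutes * spm)
  for (m in seq_len(minutes))
    sig[((m - 1L) * spm + 1L):(m * spm)] <- generateBeatTrain(labels[m])
  ECGRecording("small", 100, sig, labels)
}

# Naive peak counter: local maxima above half the signal maximum with
# a 0.25 s refractory gap.
countPeaks <- function(x, fs = 100) {
  thr <- max(x) / 2
  idx <- which(x > thr &
                 x >= c(-Inf, x[-length(x)]) &
                 x > c(x[-1], -Inf))
  if (!length(idx)) return(0L)
  keep <- c(TRUE, diff(idx) > 0.25 * fs)
  sum(keep)
}

# Brute-force AUC oracle: mean over all (apnea, normal) score pairs of
# 1 for a correctly ordered pair and 1/2 for a tie (the Mann-Whitney
# normalization).
pairwiseAuc <- function(scores, labels) {
  a <- scores[labels == "A"]
  n <- scores[labels == "N"]
  mean(outer(a, n, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Independent parameter-count oracle: spreadsheet-style enumeration of
# the reference architecture, written against the published layer
# summary before the package's closed form.
referenceParamOracle <- function() {
  conv1 <- (32 * 1 + 1) * 45
  conv2to10 <- 9 * ((32 * 45 + 1) * 45)
  bnFeature <- 10 * (4 * 45)
  fc1 <- 225 * 512 + 512
  fc2to4 <- 3 * (512 * 512 + 512)
  bnClass <- 4 * (4 * 512)
  head <- 512 * 2 + 2
  conv1 + conv2to10 + bnFeature + fc1 + fc2to4 + bnClass + head
}

# Heart-rate-variability statistic for one raw minute: the standard
# deviation of inter-peak gaps after bandpass filtering. Apnea minutes
# (cyclic rate modulation) score high, normal minutes low.
hrVarianceStat <- function(x, fs = 100) {
  y <- applyFilter(x, designBandpass(fs, 0.5, 15))
  thr <- stats::quantile(y, 0.99) / 2
  idx <- which(y > thr &
                 y >= c(-Inf, y[-length(y)]) &
                 y > c(y[-1], -Inf))
  if (length(idx) > 1) {
    keep <- idx[c(TRUE, diff(idx) > 0.25 * fs)]
    if (length(keep) > 2) return(stats::sd(diff(keep)))
  }
  0
}
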