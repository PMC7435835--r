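test_that("generation is fully deterministic given the seed", {
  cfg <- syntheticConfig(nRecords = 2, minutesPerRecord = 3, seed = 77)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(lapply(c1$records, signalValues),
                   lapply(c2$records, signalValues))
  expect_identical(c1$truth, c2$truth)
  c3 <- generateCohort(syntheticConfig(nRecords = 2, minutesPerRecord = 3,
                                       seed = 78))
  expect_false(identical(signalValues(c1$records[[1]]),
                         signalValues(c3$records[[1]])))
})

test_that("a clean constant-rate minute carries the expected number of beats", {
  set.seed(41)
  for (hr in c(60, 75)) {
    x <- generateBeatTrain("N", baseHr = hr, wanderAmp = 0, noiseSd = 0)
    # suppress the respiratory jitter contribution by regenerating the
    # minute as an apnea minute with zero swing: constant rate exactly
    xA <- generateBeatTrain("A", baseHr = hr, hrSwing = 0,
                            wanderAmp = 0, noiseSd = 0, ampModDepth = 0)
    expect_lte(abs(countPeaks(xA) - hr), 1)
    expect_identical(length(x), 6000L)
  }
})

test_that("baseline wander swamps the raw trace but not the filtered one", {
  set.seed(42)
  x <- generateBeatTrain("N", wanderAmp = 8, noiseSd = 0.01)
  co <- designBandpass(100, 0.5, 15)
  y <- applyFilter(x, co)
  # raw range is wander-dominated (~2 * 8 mV); filtered range is
  # beat-dominated (~1-2 mV)
  expect_gt(diff(range(x)), 10)
  expect_lt(diff(range(y[500:6000])), 5)
})

test_that("cohort truth matches the planted labels and spans both classes", {
  cfg <- syntheticConfig(nRecords = 6, minutesPerRecord = 20, seed = 43)
  co <- generateCohort(cfg)
  expect_length(co$records, 6)
  for (i in seq_len(6)) {
    rec <- co$records[[i]]
    expect_identical(nMinutes(rec), 20L)
    expect_equal(referenceAhi(rec),
                 60 * sum(minuteLabels(rec) == "A") / 20)
    expect_equal(co$truth$referenceAhi[i], referenceAhi(rec))
  }
  expect_setequal(unique(co$truth$osa), c("OSA", "non-OSA"))

  # all-normal cohort: no apnea minutes, all reference AHI zero
  co0 <- generateCohort(syntheticConfig(nRecords = 2, minutesPerRecord = 5,
                                        apneaFraction = 0, seed = 44))
  expect_true(all(unlist(lapply(co0$records, minuteLabels)) == "N"))
  expect_true(all(co0$truth$referenceAhi == 0))
})

test_that("apnea-minute prevalence tracks the configured fraction", {
  cfg <- syntheticConfig(nRecords = 8, minutesPerRecord = 40,
                         apneaFraction = 0.35, seed = 45)
  co <- generateCohort(cfg)
  labels <- unlist(lapply(co$records, minuteLabels))
  p <- mean(labels == "A")
  # binomial 3-sigma band around the target prevalence
  expect_lt(abs(p - 0.35), 3 * sqrt(0.35 * 0.65 / length(labels)))
})

test_that("planted labels are recoverable from heart-rate variability alone", {
  cfg <- syntheticConfig(nRecords = 4, minutesPerRecord = 15, seed = 46)
  co <- generateCohort(cfg)
  spm <- 6000L
  stats <- c(); labels <- c()
  for (rec in co$records) {
    sig <- signalValues(rec)
    labs <- minuteLabels(rec)
    for (m in seq_along(labs)) {
      stats <- c(stats, hrVarianceStat(sig[((m - 1) * spm + 1):(m * spm)]))
      labels <- c(labels, labs[m])
    }
  }
  expect_setequal(unique(labels), c("N", "A"))
  expect_gt(rocAuc(stats, labels)$auc, 0.9)
})
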