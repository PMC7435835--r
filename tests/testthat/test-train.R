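test_that("training fits an easily separable toy problem", {
  cfg <- tinyModelConfig()
  trainSet <- tinyToySegments(60, seed = 21)
  valSet <- tinyToySegments(20, seed = 22)
  tc <- trainingConfig(epochs = 12, nExperiments = 1, seeds = 1)
  res <- trainOnce(buildModel(cfg, 1), trainSet, valSet, tc, seed = 1)
  expect_s3_class(res, "experimentHistory")
  expect_identical(nrow(res$history), 12L)
  expect_gte(max(res$history$trainAccuracy), 0.95)
  # the checkpoint honours the best-validation-accuracy policy
  expect_equal(res$bestValAccuracy, max(res$history$valAccuracy))
  expect_identical(res$bestEpoch,
                   which.max(res$history$valAccuracy))
})

test_that("invalid training configurations are rejected", {
  expect_error(trainingConfig(epochs = 0), "epochs")
  expect_error(trainingConfig(nExperiments = 2, seeds = 1), "seeds")
  cfg <- tinyModelConfig()
  oneClass <- tinyToySegments(10, seed = 23)
  oneClass@labels <- rep("N", 10)
  expect_error(
    trainOnce(buildModel(cfg, 1), oneClass, oneClass,
              trainingConfig(epochs = 1, nExperiments = 1, seeds = 1)),
    "single class")
})

test_that("identical seeds reproduce identical training trajectories", {
  cfg <- tinyModelConfig()
  trainSet <- tinyToySegments(30, seed = 24)
  valSet <- tinyToySegments(10, seed = 25)
  tc <- trainingConfig(epochs = 2, nExperiments = 1, seeds = 9)
  r1 <- trainOnce(buildModel(cfg, 9), trainSet, valSet, tc, seed = 9)
  r2 <- trainOnce(buildModel(cfg, 9), trainSet, valSet, tc, seed = 9)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@weights, r2$model@weights)
  # a different seed gives a different first-epoch loss
  r3 <- trainOnce(buildModel(cfg, 10), trainSet, valSet, tc, seed = 10)
  expect_false(identical(r1$history$trainLoss[1], r3$history$trainLoss[1]))
})

test_that("labels never leak into inference", {
  cfg <- tinyModelConfig()
  trainSet <- tinyToySegments(30, seed = 26)
  valSet <- tinyToySegments(16, seed = 27)
  tc <- trainingConfig(epochs = 2, nExperiments = 1, seeds = 4)
  res <- trainOnce(buildModel(cfg, 4), trainSet, valSet, tc, seed = 4)
  pred <- predictLabels(res$model, valSet)
  # shuffling validation labels changes the reported accuracy but not
  # one prediction
  shuffled <- valSet
  set.seed(1)
  shuffled@labels <- sample(valSet@labels)
  predShuffled <- predictLabels(res$model, shuffled)
  expect_identical(pred, predShuffled)
})

test_that("repeated experiments select the best checkpoint with stable ties", {
  cfg <- tinyModelConfig()
  trainSet <- tinyToySegments(30, seed = 28)
  valSet <- tinyToySegments(10, seed = 29)
  tc3 <- trainingConfig(epochs = 2, nExperiments = 3, seeds = c(5, 6, 7))
  series <- runExperiments(trainSet, valSet, cfg, tc3)
  expect_length(series$experiments, 3)
  expect_equal(max(series$bestValAccuracies),
               series$experiments[[series$bestIndex]]$bestValAccuracy)
  # the reported spread is the range over experiments
  expect_equal(series$spread, range(series$bestValAccuracies))
  # which.max takes the lowest index among ties
  expect_identical(series$bestIndex,
                   which.max(series$bestValAccuracies))

  # a single experiment reduces to trainOnce under the same seed
  tc1 <- trainingConfig(epochs = 2, nExperiments = 1, seeds = 5)
  solo <- runExperiments(trainSet, valSet, cfg, tc1)
  direct <- trainOnce(buildModel(cfg, 5), trainSet, valSet, tc1, seed = 5)
  expect_identical(solo$experiments[[1]]$history, direct$history)
  expect_identical(solo$bestModel@weights, direct$model@weights)
})
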