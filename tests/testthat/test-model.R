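test_that("pooled length follows iterated floor halving", {
  expect_identical(pooledLength(6000, 10), 5L)
  expect_identical(pooledLength(375, 1), 187L)
  expect_identical(pooledLength(1234, 0), 1234L)
  expect_error(pooledLength(4, 3), "empties")
})

test_that("shape table reproduces the reference 10-layer architecture", {
  tab <- shapeTable(modelConfig())
  # the pooled-length chain 6000 -> ... -> 11 -> 5
  pools <- tab[grepl("^pool", tab$layer), ]
  expect_equal(pools$length,
               c(3000, 1500, 750, 375, 187, 93, 46, 23, 11, 5))
  expect_true(all(pools$channels == 45))
  # layer-10 convolution sees length 11
  expect_equal(tab[tab$layer == "conv10", c("length", "channels")],
               data.frame(length = 11, channels = 45, row.names = 46L),
               ignore_attr = TRUE)
  expect_equal(tab[tab$layer == "flatten", "length"], 225)
  fc <- tab[grepl("^fc", tab$layer), ]
  expect_equal(fc$length, rep(512, 4))
  expect_equal(tab[tab$layer == "softmax", "length"], 2)

  # one halving only
  tab1 <- shapeTable(modelConfig(nFeatureLayers = 1))
  expect_equal(tab1[tab1$layer == "pool1", c("length", "channels")],
               data.frame(length = 3000, channels = 45),
               ignore_attr = TRUE)
})

test_that("parameter count matches the independent enumeration oracle", {
  cfg <- modelConfig()
  expect_identical(countParameters(cfg), as.integer(referenceParamOracle()))
  expect_equal(round(countParameters(cfg) / 1e6, 1), 1.5)
  # trainable-only drops the 2 moving statistics per BN channel
  expect_identical(countParameters(cfg) - countParameters(cfg, TRUE),
                   as.integer(2 * (10 * 45 + 4 * 512)))
  # degenerate base case: no feature or classification layers
  cfg0 <- modelConfig(nFeatureLayers = 0, nClassLayers = 0,
                      inputLength = 100)
  expect_identical(countParameters(cfg0), as.integer(101 * 2))
})

test_that("built models agree with the analytic count and are seed-reproducible", {
  cfg <- tinyModelConfig()
  m1 <- buildModel(cfg, seed = 42)
  m2 <- buildModel(cfg, seed = 42)
  m3 <- buildModel(cfg, seed = 43)
  expect_identical(modelParameterCount(m1), countParameters(cfg))
  expect_identical(modelParameterCount(m1, trainableOnly = TRUE),
                   countParameters(cfg, trainableOnly = TRUE))
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m1@weights, m3@weights))

  # He-normal scaling: empirical sd of the first conv kernel matches
  # sqrt(2 / fanIn) (fanIn = kernelSize * inChannels)
  cfgBig <- modelConfig(nFeatureLayers = 1, nFilters = 200,
                        kernelSize = 32, nClassLayers = 0,
                        inputLength = 64)
  mBig <- buildModel(cfgBig, seed = 1)
  expect_equal(sd(mBig@weights[["f1.W"]]), sqrt(2 / 32),
               tolerance = 0.05)
})

test_that("inference is a deterministic probability vector per segment", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 3)
  set.seed(30)
  X <- matrix(rnorm(7 * cfg@inputLength), 7)
  p1 <- predictSegments(m, X)
  p2 <- predictSegments(m, X)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batching is a memory knob, not a result knob
  expect_equal(predictSegments(m, X, batchSize = 2), p1,
               tolerance = 1e-12)
  # wrong segment width is caught
  expect_error(predictSegments(m, X[, 1:100]), "expects")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- modelConfig(nFeatureLayers = 2, nFilters = 3, kernelSize = 5,
                     nClassLayers = 1, fcUnits = 6, inputLength = 24,
                     dropoutRate = 0)   # deterministic loss surface
  m <- buildModel(cfg, seed = 7)
  ns <- asNamespace("apneaCNN")
  set.seed(99)
  X <- matrix(rnorm(4 * 24), 4, 24)
  y <- c(1L, 2L, 1L, 2L)
  fw <- ns$.cnnForward(m@weights, cfg, X, training = TRUE)
  gr <- ns$.cnnBackward(m@weights, cfg, fw, y)
  lossAt <- function(w)
    ns$.crossEntropy(ns$.cnnForward(w, cfg, X, training = TRUE)$probs, y)
  h <- 1e-5
  for (nm in names(gr)) {
    w <- m@weights
    for (i in sample(length(w[[nm]]), min(3, length(w[[nm]])))) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      numeric <- (lossAt(wp) - lossAt(wm)) / (2 * h)
      expect_equal(gr[[nm]][i], numeric, tolerance = 1e-3,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints and descriptors round-trip", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 12)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  saveModel(m, path)
  expect_true(file.exists(file.path(dir, "model_architecture.json")))
  back <- loadModel(path)
  expect_identical(back@weights, m@weights)
  desc <- jsonlite::fromJSON(architectureDescriptor(m))
  expect_equal(desc$nParameters, countParameters(cfg))
  expect_equal(desc$config$init, "he_normal")
})
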