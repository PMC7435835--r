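## Training protocol: minibatch Adam on categorical cross-entropy with
## per-epoch validation and best-validation-accuracy checkpointing,
## repeated over independent experiments (fresh He-normal
## initialization per experiment). Reference protocol: batch size 10,
## 50 epochs, 10 experiments.

#' Train a model once with best-validation checkpointing
#'
#' Runs minibatch Adam on softmax cross-entropy for `epochs` epochs.
#' Per epoch, training loss/accuracy are averaged over minibatches (in
#' training mode, i.e. with dropout active and batch statistics), while
#' validation loss/accuracy come from a full deterministic inference
#' pass; the two are therefore not directly comparable early in
#' training. The weights of the epoch with the highest validation
#' accuracy are kept (first such epoch on ties). All randomness (batch
#' order, dropout) derives from `seed`, so identical calls reproduce
#' identical histories.
#'
#' @param model an [ApneaCNN-class] starting point (see [buildModel()]).
#' @param trainSet,valSet [MinuteSegmentSet-class] objects; the
#'   training set must contain both classes.
#' @param config a [TrainingConfig-class].
#' @param seed integer seed for batch shuffling and dropout.
#' @param verbose print a line per epoch.
#' @return A list of class `"experimentHistory"`: `history` (one row
#'   per epoch: `epoch`, `trainLoss`, `trainAccuracy`, `valLoss`,
#'   `valAccuracy`), `bestEpoch`, `bestValAccuracy`, and `model`, the
#'   checkpointed [ApneaCNN-class].
#' @export
trainOnce <- function(model, trainSet, valSet, config = trainingConfig(),
                      seed = 1L, verbose = FALSE) {
  stopifnot(is(model, "ApneaCNN"), is(trainSet, "MinuteSegmentSet"),
            is(valSet, "MinuteSegmentSet"), is(config, "TrainingConfig"))
  validObject(config)
  yTrain <- match(segmentLabels(trainSet), .LABEL_LEVELS)
  yVal <- match(segmentLabels(valSet), .LABEL_LEVELS)
  if (length(unique(yTrain)) < 2L)
    stop("training set contains a single class; both N and A are required")

  Xtr <- segmentMatrix(trainSet)
  Xval <- segmentMatrix(valSet)
  cfg <- model@config
  w <- model@weights
  adam <- .adamInit(w)
  n <- nrow(Xtr)
  set.seed(as.integer(seed))

  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     trainAccuracy = numeric(), valLoss = numeric(),
                     valAccuracy = numeric())
  bestAcc <- -Inf
  bestEpoch <- NA_integer_
  bestW <- w

  for (epoch in seq_len(config@epochs)) {
    ord <- sample.int(n)
    lossSum <- 0; accSum <- 0; nb <- 0L
    for (start in seq(1L, n, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, n)]
      fw <- .cnnForward(w, cfg, Xtr[idx, , drop = FALSE],
                        training = TRUE)
      loss <- .crossEntropy(fw$probs, yTrain[idx])
      if (!is.finite(loss))
        stop(sprintf(
          "non-finite training loss at epoch %d, batch %d; aborting (inspect the learning rate and input scaling)",
          epoch, nb + 1L))
      grads <- .cnnBackward(w, cfg, fw, yTrain[idx])
      for (nm in names(fw$stats)) w[[nm]] <- fw$stats[[nm]]
      upd <- .adamStep(w, grads, adam, config)
      w <- upd$w
      adam <- upd$state
      lossSum <- lossSum + loss
      accSum <- accSum +
        mean((fw$probs[2L, ] > 0.5) == (yTrain[idx] == 2L))
      nb <- nb + 1L
    }
    ev <- .evaluatePass(w, cfg, Xval, yVal, config@batchSize)
    hist[epoch, ] <- list(epoch, lossSum / nb, accSum / nb,
                          ev$loss, ev$accuracy)
    if (ev$accuracy > bestAcc) {
      bestAcc <- ev$accuracy
      bestEpoch <- epoch
      bestW <- w
    }
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
        epoch, hist$trainLoss[epoch], hist$trainAccuracy[epoch],
        ev$loss, ev$accuracy))
  }

  structure(list(
    history = hist, bestEpoch = bestEpoch, bestValAccuracy = bestAcc,
    model = new("ApneaCNN", config = cfg, weights = bestW,
                seed = model@seed)),
    class = "experimentHistory")
}

.evaluatePass <- function(w, cfg, X, y, batchSize) {
  n <- nrow(X)
  lossSum <- 0; correct <- 0
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fw <- .cnnForward(w, cfg, X[idx, , drop = FALSE], training = FALSE,
                      cache = FALSE)
    lossSum <- lossSum + .crossEntropy(fw$probs, y[idx]) * length(idx)
    correct <- correct + sum((fw$probs[2L, ] > 0.5) == (y[idx] == 2L))
  }
  list(loss = lossSum / n, accuracy = correct / n)
}

#' @export
print.experimentHistory <- function(x, ...) {
  cat(sprintf(
    "experimentHistory: %d epoch(s); best validation accuracy %.4f at epoch %d\n",
    nrow(x$history), x$bestValAccuracy, x$bestEpoch))
  invisible(x)
}

#' Repeat independent training experiments and keep the best model
#'
#' Runs `config@nExperiments` trainings, each from a fresh He-normal
#' initialization seeded by the corresponding entry of `config@seeds`
#' (the same seed also drives that experiment's batch order and
#' dropout). The checkpoint with the maximum best validation accuracy
#' is selected; ties go to the lowest experiment index.
#'
#' @param trainSet,valSet [MinuteSegmentSet-class] objects.
#' @param modelCfg a [ModelConfig-class] used for every experiment.
#' @param config a [TrainingConfig-class].
#' @param verbose print per-epoch progress.
#' @return A list of class `"experimentSeries"`: `experiments` (list of
#'   `"experimentHistory"`), `bestIndex`, `bestModel`,
#'   `bestValAccuracies` (one per experiment) and `spread`
#'   (their range).
#' @export
runExperiments <- function(trainSet, valSet, modelCfg = modelConfig(),
                           config = trainingConfig(), verbose = FALSE) {
  stopifnot(is(modelCfg, "ModelConfig"), is(config, "TrainingConfig"))
  validObject(config)
  experiments <- vector("list", config@nExperiments)
  for (i in seq_len(config@nExperiments)) {
    s <- config@seeds[i]
    model <- buildModel(modelCfg, seed = s)
    experiments[[i]] <- trainOnce(model, trainSet, valSet, config,
                                  seed = s, verbose = verbose)
  }
  accs <- vapply(experiments, function(e) e$bestValAccuracy, numeric(1))
  best <- which.max(accs)   # first maximum = lowest index on ties
  structure(list(
    experiments = experiments, bestIndex = best,
    bestModel = experiments[[best]]$model,
    bestValAccuracies = accs, spread = range(accs)),
    class = "experimentSeries")
}

#' @export
print.experimentSeries <- function(x, ...) {
  cat(sprintf(
    "experimentSeries: %d experiment(s); best validation accuracy %.4f (experiment %d); spread %.4f-%.4f\n",
    length(x$experiments), max(x$bestValAccuracies), x$bestIndex,
    x$spread[1], x$spread[2]))
  invisible(x)
}

#' Export a training history as CSV
#'
#' @param result an `"experimentHistory"` from [trainOnce()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportHistory <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
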