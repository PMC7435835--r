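## Architecture arithmetic and model construction.

#' Feature-map length after repeated max pooling
#'
#' Applies `floor(n / 2)` iteratively `layers` times, the length
#' arithmetic of stride-2 pooling; in the reference network the
#' 6000-sample input shrinks 6000 -> 3000 -> ... -> 11 -> 5 over the 10
#' feature-extraction layers.
#'
#' @param n input length in samples, `>= 1`.
#' @param layers number of pooling layers, `>= 0`.
#' @return The pooled length.
#' @examples
#' pooledLength(6000, 10)  # 5
#' @export
pooledLength <- function(n, layers) {
  stopifnot(n >= 1, layers >= 0)
  n <- as.integer(n)
  for (i in seq_len(layers)) n <- n %/% 2L
  if (n < 1L)
    stop(sprintf("pooling %d time(s) empties a length-%d input",
                 layers, as.integer(n)))
  n
}

#' Layer-by-layer output shapes of the network
#'
#' Analytic shape table, one row per layer: convolutions use 'same'
#' padding (length preserved), batch normalization / activation /
#' dropout preserve shape, max pooling halves length (floor), flatten
#' multiplies length by channels.
#'
#' @param cfg a [ModelConfig-class].
#' @return A data.frame with columns `layer`, `length`, `channels`.
#'   For flatten and the fully connected layers, `length` is the
#'   feature width and `channels` is 1.
#' @examples
#' tab <- shapeTable(modelConfig())
#' tab[tab$layer == "flatten", ]   # width 225
#' @export
shapeTable <- function(cfg) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  rows <- list(data.frame(layer = "input", length = cfg@inputLength,
                          channels = 1L))
  L <- cfg@inputLength
  for (l in seq_len(cfg@nFeatureLayers)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d", l), length = L, channels = cfg@nFilters)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("bn%d", l), length = L, channels = cfg@nFilters)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("relu%d", l), length = L, channels = cfg@nFilters)
    L <- L %/% 2L
    if (L < 1L) stop("too many feature layers for the input length")
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("pool%d", l), length = L, channels = cfg@nFilters)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("dropout%d", l), length = L, channels = cfg@nFilters)
  }
  flatC <- if (cfg@nFeatureLayers > 0L) cfg@nFilters else 1L
  width <- L * flatC
  rows[[length(rows) + 1L]] <- data.frame(layer = "flatten",
                                          length = width, channels = 1L)
  for (l in seq_len(cfg@nClassLayers))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("fc%d", l), length = cfg@fcUnits, channels = 1L)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "softmax", length = cfg@nOutputs, channels = 1L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total parameter count of the network
#'
#' Closed-form sum over layers: each convolution contributes
#' `(kernelSize * inChannels + 1) * nFilters` weights-plus-biases and
#' its batch normalization `4 * nFilters` parameters (scale, shift,
#' moving mean, moving variance); each classification block
#' contributes `(fanIn + 1) * fcUnits` plus `4 * fcUnits`; the softmax
#' head contributes `(fanIn + 1) * nOutputs`. The reference 10-layer
#' configuration totals 1,499,788 parameters, i.e. about 1.5 million.
#'
#' @param cfg a [ModelConfig-class].
#' @param trainableOnly if `TRUE`, exclude the batch-normalization
#'   moving statistics (2 of the 4 per-channel parameters).
#' @return Integer parameter count.
#' @examples
#' round(countParameters(modelConfig()) / 1e6, 1)  # 1.5
#' @export
countParameters <- function(cfg, trainableOnly = FALSE) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  bnPer <- if (trainableOnly) 2 else 4
  total <- 0
  cin <- 1L
  L <- cfg@inputLength
  for (l in seq_len(cfg@nFeatureLayers)) {
    total <- total + (cfg@kernelSize * cin + 1) * cfg@nFilters +
      bnPer * cfg@nFilters
    cin <- cfg@nFilters
    L <- L %/% 2L
  }
  fanIn <- L * (if (cfg@nFeatureLayers > 0L) cfg@nFilters else 1L)
  for (l in seq_len(cfg@nClassLayers)) {
    total <- total + (fanIn + 1) * cfg@fcUnits + bnPer * cfg@fcUnits
    fanIn <- cfg@fcUnits
  }
  total <- total + (fanIn + 1) * cfg@nOutputs
  as.integer(total)
}

#' Build a trainable model with He-normal initialization
#'
#' Instantiates all weight tensors for the architecture described by
#' `cfg`: per feature-extraction layer a convolution (weights drawn
#' He-normal, i.e. `N(0, 2/fanIn)` with `fanIn = kernelSize *
#' inChannels`, biases zero) and batch normalization (scale 1, shift 0,
#' moving mean 0, moving variance 1); per classification layer a fully
#' connected map (He-normal over its fan-in) and batch normalization;
#' and a final softmax head. Two builds from the same seed are
#' identical.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed integer seed for the weight draws.
#' @return An [ApneaCNN-class] model.
#' @examples
#' m <- buildModel(modelConfig(nFeatureLayers = 2, inputLength = 200,
#'                             nClassLayers = 1, fcUnits = 16), seed = 1)
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  if (length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  seed <- as.integer(seed)
  set.seed(seed)
  w <- list()
  cin <- 1L
  L <- cfg@inputLength
  nf <- cfg@nFilters
  for (l in seq_len(cfg@nFeatureLayers)) {
    p <- paste0("f", l)
    fanIn <- cfg@kernelSize * cin
    w[[paste0(p, ".W")]] <- matrix(
      stats::rnorm(fanIn * nf, sd = sqrt(2 / fanIn)), fanIn, nf)
    w[[paste0(p, ".b")]] <- numeric(nf)
    w[[paste0(p, ".gamma")]] <- rep(1, nf)
    w[[paste0(p, ".beta")]] <- numeric(nf)
    w[[paste0(p, ".rmean")]] <- numeric(nf)
    w[[paste0(p, ".rvar")]] <- rep(1, nf)
    cin <- nf
    L <- L %/% 2L
  }
  fanIn <- L * (if (cfg@nFeatureLayers > 0L) nf else 1L)
  for (l in seq_len(cfg@nClassLayers)) {
    p <- paste0("c", l)
    U <- cfg@fcUnits
    w[[paste0(p, ".W")]] <- matrix(
      stats::rnorm(fanIn * U, sd = sqrt(2 / fanIn)), fanIn, U)
    w[[paste0(p, ".b")]] <- numeric(U)
    w[[paste0(p, ".gamma")]] <- rep(1, U)
    w[[paste0(p, ".beta")]] <- numeric(U)
    w[[paste0(p, ".rmean")]] <- numeric(U)
    w[[paste0(p, ".rvar")]] <- rep(1, U)
    fanIn <- U
  }
  w[["head.W"]] <- matrix(
    stats::rnorm(fanIn * cfg@nOutputs, sd = sqrt(2 / fanIn)),
    fanIn, cfg@nOutputs)
  w[["head.b"]] <- numeric(cfg@nOutputs)
  new("ApneaCNN", config = cfg, weights = w, seed = seed)
}

#' Parameter count of a built model
#'
#' Sums the sizes of the instantiated weight tensors; equals
#' [countParameters()] of the model's configuration.
#'
#' @param model an [ApneaCNN-class].
#' @param trainableOnly exclude batch-normalization moving statistics.
#' @return Integer count.
#' @export
modelParameterCount <- function(model, trainableOnly = FALSE) {
  stopifnot(is(model, "ApneaCNN"))
  nm <- names(model@weights)
  if (trainableOnly)
    nm <- grep("\\.(rmean|rvar)$", nm, invert = TRUE, value = TRUE)
  as.integer(sum(vapply(model@weights[nm], length, numeric(1))))
}

#' Class probabilities for a set of segments
#'
#' Deterministic inference pass (batch-normalization uses moving
#' statistics; dropout is inactive). Rows sum to 1.
#'
#' @param model an [ApneaCNN-class].
#' @param segments a [MinuteSegmentSet-class] or a numeric matrix with
#'   one segment per row.
#' @param batchSize segments per forward pass (memory knob, not a
#'   result knob).
#' @return Numeric matrix, one row per segment, columns `"N"`, `"A"`.
#' @export
predictSegments <- function(model, segments, batchSize = 25L) {
  stopifnot(is(model, "ApneaCNN"))
  X <- if (is(segments, "MinuteSegmentSet")) segmentMatrix(segments)
       else as.matrix(segments)
  if (ncol(X) != model@config@inputLength)
    stop(sprintf("segments have %d samples but the model expects %d",
                 ncol(X), model@config@inputLength))
  n <- nrow(X)
  probs <- matrix(NA_real_, n, model@config@nOutputs,
                  dimnames = list(NULL, .LABEL_LEVELS))
  for (start in seq(1L, n, by = batchSize)) {
    end <- min(start + batchSize - 1L, n)
    fw <- .cnnForward(model@weights, model@config,
                      X[start:end, , drop = FALSE], training = FALSE)
    probs[start:end, ] <- t(fw$probs)
  }
  probs
}

#' Hard labels from class probabilities
#'
#' Predicts `"A"` when the apnea probability exceeds 0.5 (the class
#' with the greater probability); an exact tie predicts `"N"`.
#'
#' @param model an [ApneaCNN-class].
#' @param segments segments as in [predictSegments()].
#' @param probs optionally, an already computed probability matrix.
#' @return Character vector of `"N"`/`"A"`.
#' @export
predictLabels <- function(model, segments = NULL, probs = NULL) {
  if (is.null(probs)) probs <- predictSegments(model, segments)
  ifelse(probs[, "A"] > 0.5, "A", "N")
}

#' Framework-neutral architecture descriptor
#'
#' Serializes the configuration and the shape table as JSON; a weight
#' checkpoint can be saved next to it with [saveModel()].
#'
#' @param model an [ApneaCNN-class] (or a bare [ModelConfig-class]).
#' @param path optional file to write.
#' @return JSON string (invisibly when written to file).
#' @export
architectureDescriptor <- function(model, path = NULL) {
  cfg <- if (is(model, "ApneaCNN")) model@config else model
  desc <- list(
    config = list(
      nFeatureLayers = cfg@nFeatureLayers, nFilters = cfg@nFilters,
      kernelSize = cfg@kernelSize, poolSize = cfg@poolSize,
      poolStride = cfg@poolStride, dropoutRate = cfg@dropoutRate,
      nClassLayers = cfg@nClassLayers, fcUnits = cfg@fcUnits,
      nOutputs = cfg@nOutputs, inputLength = cfg@inputLength,
      bnMomentum = cfg@bnMomentum, bnEpsilon = cfg@bnEpsilon,
      init = "he_normal"),
    nParameters = countParameters(cfg),
    nParametersTrainable = countParameters(cfg, trainableOnly = TRUE),
    shapes = shapeTable(cfg))
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Save / load a model checkpoint
#'
#' `saveModel()` writes the full model (configuration + weights,
#' including batch-normalization moving statistics) as an RDS
#' checkpoint and a JSON architecture descriptor next to it;
#' `loadModel()` reads the checkpoint back.
#'
#' @param model an [ApneaCNN-class].
#' @param path checkpoint path (`.rds`).
#' @return `saveModel()` the path invisibly; `loadModel()` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ApneaCNN"))
  saveRDS(model, path)
  architectureDescriptor(model, paste0(sub("\\.rds$", "", path),
                                       "_architecture.json"))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "ApneaCNN")) stop("not an ApneaCNN checkpoint: ", path)
  model
}
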