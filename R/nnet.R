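## Native 1D-CNN engine.
##
## Activations flow through the network channels-first: a minibatch of
## B segments of length L with C channels is a (C x B*L) matrix whose
## column (b-1)*L + l holds item b at time l. This layout makes every
## per-channel broadcast (convolution bias, batch normalization) a
## cheap row-recycled vector operation, lets 'same'-padded convolution
## run as K offset BLAS GEMMs against the (C*K x F) weight matrix with
## no materialized im2col buffer (src/conv1d.c), and makes flatten a
## plain reshape. Batch normalization therefore normalizes each channel over
## batch x time (the Keras convention for (None, L, C) tensors), max
## pooling is a pairwise maximum over precomputed column indices, and
## dropout is "inverted" (activations scaled by 1/keep during
## training, identity at inference). All randomness (initialization,
## batch shuffling, dropout masks) comes from R's RNG stream, so
## set.seed() makes builds and training runs bit-reproducible.

.LABEL_LEVELS <- c("N", "A")   # class 1 = N, class 2 = A

.convForward <- function(A, W, bias, B, L, K) {
  .Call(C_conv1d_fwd, A, W, bias, as.integer(B), as.integer(L),
        as.integer(K))
}

.convBackward <- function(A, W, dOut, B, L, K) {
  list(gW = .Call(C_conv1d_bwd_weights, A, dOut, as.integer(B),
                  as.integer(L), as.integer(K)),
       gB = rowSums(dOut),
       dX = .Call(C_conv1d_bwd_data, W, dOut, as.integer(B),
                  as.integer(L), as.integer(K)))
}

## Batch normalization over columns, per row (= per channel).
.bnForward <- function(X, gamma, beta, rmean, rvar, eps, momentum,
                       training) {
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * invstd
    list(out = xhat * gamma + beta, xhat = xhat, invstd = invstd,
         rmean = momentum * rmean + (1 - momentum) * mu,
         rvar = momentum * rvar + (1 - momentum) * v)
  } else {
    invstd <- 1 / sqrt(rvar + eps)
    list(out = (X - rmean) * (gamma * invstd) + beta)
  }
}

.bnBackward <- function(cache, gamma, dY) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## Max pooling (size 2, stride 2) over the time axis; a trailing odd
## sample is dropped. Column indices are a function of (B, L) only.
.poolIndex <- function(B, L) {
  Lout <- L %/% 2L
  tpos <- seq(1L, 2L * Lout, by = 2L)
  offs <- rep((0:(B - 1L)) * L, each = Lout)
  i1 <- rep(tpos, times = B) + offs
  list(i1 = i1, i2 = i1 + 1L, Lout = Lout)
}

.poolForward <- function(X, B, L) {
  px <- .poolIndex(B, L)
  X1 <- X[, px$i1, drop = FALSE]
  X2 <- X[, px$i2, drop = FALSE]
  take <- X1 >= X2            # ties keep the earlier sample
  list(out = pmax(X1, X2), take = take, i1 = px$i1,
       i2 = px$i2, inCols = B * L, Lout = px$Lout)
}

.poolBackward <- function(cache, dOut) {
  dX <- matrix(0, nrow(dOut), cache$inCols)
  dX[, cache$i1] <- dOut * cache$take
  dX[, cache$i2] <- dOut * !cache$take
  dX
}

.dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X))
  list(out = X * mask / keep, mask = mask, keep = keep)
}

.softmaxCols <- function(Z) {
  Zs <- sweep(Z, 2L, apply(Z, 2L, max), "-")
  P <- exp(Zs)
  sweep(P, 2L, colSums(P), "/")
}

## Full forward pass.
## X: B x inputLength matrix of standardized segments (one per row).
## Returns column-wise class probabilities (nOutputs x B) plus, when
## caching, everything the backward pass needs and the updated BN
## running statistics.
.cnnForward <- function(w, cfg, X, training = FALSE, cache = training) {
  B <- nrow(X)
  caches <- list()
  stats <- list()
  act <- matrix(as.vector(t(X)), nrow = 1L)   # 1 x (B*L), channels-first
  L <- cfg@inputLength
  K <- cfg@kernelSize

  for (l in seq_len(cfg@nFeatureLayers)) {
    p <- paste0("f", l)
    Ain <- act
    z <- .convForward(Ain, w[[paste0(p, ".W")]], w[[paste0(p, ".b")]],
                      B, L, K)
    bn <- .bnForward(z, w[[paste0(p, ".gamma")]],
                     w[[paste0(p, ".beta")]], w[[paste0(p, ".rmean")]],
                     w[[paste0(p, ".rvar")]], cfg@bnEpsilon,
                     cfg@bnMomentum, training)
    relu <- bn$out > 0
    pl <- .poolForward(bn$out * relu, B, L)
    dr <- .dropoutForward(pl$out, cfg@dropoutRate, training)
    act <- dr$out
    if (cache) {
      caches[[p]] <- list(Ain = Ain, bn = bn[c("xhat", "invstd")],
                          relu = relu,
                          pool = pl[c("take", "i1", "i2", "inCols")],
                          drop = dr[c("mask", "keep")], L = L)
      stats[[paste0(p, ".rmean")]] <- bn$rmean
      stats[[paste0(p, ".rvar")]] <- bn$rvar
    }
    L <- pl$Lout
  }

  flatC <- if (cfg@nFeatureLayers > 0L) cfg@nFilters else 1L
  flatL <- L
  dim(act) <- c(flatC * L, B)                 # flatten: reshape only

  for (l in seq_len(cfg@nClassLayers)) {
    p <- paste0("c", l)
    Xin <- act
    z <- crossprod(w[[paste0(p, ".W")]], Xin) + w[[paste0(p, ".b")]]
    bn <- .bnForward(z, w[[paste0(p, ".gamma")]], w[[paste0(p, ".beta")]],
                     w[[paste0(p, ".rmean")]], w[[paste0(p, ".rvar")]],
                     cfg@bnEpsilon, cfg@bnMomentum, training)
    relu <- bn$out > 0
    dr <- .dropoutForward(bn$out * relu, cfg@dropoutRate, training)
    act <- dr$out
    if (cache) {
      caches[[p]] <- list(Xin = Xin, bn = bn[c("xhat", "invstd")],
                          relu = relu, drop = dr[c("mask", "keep")])
      stats[[paste0(p, ".rmean")]] <- bn$rmean
      stats[[paste0(p, ".rvar")]] <- bn$rvar
    }
  }

  logits <- crossprod(w[["head.W"]], act) + w[["head.b"]]
  probs <- .softmaxCols(logits)               # nOutputs x B
  list(probs = probs, caches = caches, stats = stats, headIn = act,
       B = B, flatL = flatL, flatC = flatC)
}

## Backward pass from softmax cross-entropy.
## y: integer class labels in 1..nOutputs. Returns gradients named as
## the weights (trainable entries only).
.cnnBackward <- function(w, cfg, fw, y) {
  B <- fw$B
  grads <- list()
  Y <- matrix(0, cfg@nOutputs, B)
  Y[cbind(y, seq_len(B))] <- 1
  dZ <- (fw$probs - Y) / B                    # nOutputs x B

  grads[["head.W"]] <- tcrossprod(fw$headIn, dZ)
  grads[["head.b"]] <- rowSums(dZ)
  dAct <- w[["head.W"]] %*% dZ

  for (l in rev(seq_len(cfg@nClassLayers))) {
    p <- paste0("c", l)
    cc <- fw$caches[[p]]
    if (!is.null(cc$drop$mask)) dAct <- dAct * cc$drop$mask / cc$drop$keep
    dAct <- dAct * cc$relu
    bb <- .bnBackward(cc$bn, w[[paste0(p, ".gamma")]], dAct)
    grads[[paste0(p, ".gamma")]] <- bb$dgamma
    grads[[paste0(p, ".beta")]] <- bb$dbeta
    grads[[paste0(p, ".W")]] <- tcrossprod(cc$Xin, bb$dX)
    grads[[paste0(p, ".b")]] <- rowSums(bb$dX)
    dAct <- w[[paste0(p, ".W")]] %*% bb$dX
  }

  dim(dAct) <- c(fw$flatC, fw$flatL * B)      # unflatten

  for (l in rev(seq_len(cfg@nFeatureLayers))) {
    p <- paste0("f", l)
    cc <- fw$caches[[p]]
    if (!is.null(cc$drop$mask)) dAct <- dAct * cc$drop$mask / cc$drop$keep
    dAct <- .poolBackward(cc$pool, dAct)
    dAct <- dAct * cc$relu
    bb <- .bnBackward(cc$bn, w[[paste0(p, ".gamma")]], dAct)
    grads[[paste0(p, ".gamma")]] <- bb$dgamma
    grads[[paste0(p, ".beta")]] <- bb$dbeta
    cb <- .convBackward(cc$Ain, w[[paste0(p, ".W")]], bb$dX,
                        B, cc$L, cfg@kernelSize)
    grads[[paste0(p, ".W")]] <- cb$gW
    grads[[paste0(p, ".b")]] <- cb$gB
    dAct <- cb$dX
  }
  grads
}

## probs: nOutputs x B (columns are items).
.crossEntropy <- function(probs, y) {
  p <- probs[cbind(y, seq_len(ncol(probs)))]
  -mean(log(pmax(p, 1e-12)))
}

.adamInit <- function(w) {
  trainable <- grep("\\.(rmean|rvar)$", names(w), invert = TRUE,
                    value = TRUE)
  list(t = 0L,
       m = lapply(w[trainable], function(x) x * 0),
       v = lapply(w[trainable], function(x) x * 0))
}

.adamStep <- function(w, grads, state, tc) {
  state$t <- state$t + 1L
  lr <- tc@learningRate
  b1 <- tc@beta1; b2 <- tc@beta2; eps <- tc@epsilon
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(w = w, state = state)
}
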