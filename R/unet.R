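## A tiny two-level U-Net (encoder conv pair, 2x2 maxpool, bottleneck conv,
## nearest-neighbour upsample, skip concatenation, decoder conv, 1x1
## classifier, softmax) with hand-written forward/backward passes built on
## im2col matrix multiplication. Feature maps are (H*W x channels) matrices;
## all gather/scatter index maps are precomputed per resolution. This is the
## default differentiable backend behind the training harness's adapter
## contract; any other backend honouring the same contract can replace it.

## neighbour index map for 3x3 zero-padded convolution at resolution (H, W):
## entry [pix, k] is the source pixel row for kernel offset k, or N+1 for
## the zero-padding row
.convIndex3 <- function(H, W) {
  N <- H * W
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  idx <- matrix(N + 1L, N, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    idx[ok, k] <- (c2[ok] - 1L) * H + r2[ok]
  }
  idx
}

## 2x2 maxpool child map: [pool cell, 1:4] source rows at resolution (H, W)
.poolIndex2 <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- rep(seq_len(Ho), Wo)
  co <- rep(seq_len(Wo), each = Ho)
  base <- function(dr, dc) (2L * (co - 1L) + dc - 1L) * H + (2L * (ro - 1L) + dr)
  cbind(base(1L, 1L), base(2L, 1L), base(1L, 2L), base(2L, 2L))
}

## nearest upsample map: output row -> input row (input is H/2 x W/2)
.upIndex2 <- function(H, W) {
  Hi <- H %/% 2L
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  (ceiling(cc / 2) - 1L) * Hi + ceiling(rr / 2)
}

.im2col <- function(x, idx) {
  ## x: (N x Cin) feature matrix; returns (N x 9*Cin), kernel offset fastest
  xx <- rbind(x, 0)
  matrix(xx[as.vector(idx), , drop = FALSE], nrow = nrow(x))
}

.col2im <- function(dX, idx, N, Cin) {
  dF <- matrix(0, N, Cin)
  for (k in 1:9) {
    src <- idx[, k]
    ok <- src <= N
    cols <- k + 9L * (seq_len(Cin) - 1L)
    dF[src[ok], ] <- dF[src[ok], ] + dX[ok, cols, drop = FALSE]
  }
  dF
}

.xavier <- function(fanIn, fanOut, nr, nc) {
  s <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build a tiny U-Net model
#'
#' Constructs the parameter set and index maps of a two-level U-Net for
#' dense classification of a 2-D single-channel image: two 3x3 encoder
#' convolutions (`baseFilters` channels), 2x2 max pooling, a 3x3 bottleneck
#' convolution (`2 * baseFilters`), nearest-neighbour upsampling with skip
#' concatenation, a 3x3 decoder convolution and a 1x1 softmax classifier.
#' Weights use Xavier (uniform) initialisation, deterministic given `seed`.
#'
#' @param inputShape `c(H, W)` with even `H`, `W`.
#' @param nClasses number of output classes.
#' @param baseFilters encoder width; default 8 (bottleneck is twice that).
#' @param seed integer RNG seed for the initialisation.
#' @return A model object (list) accepted by [unetForward()],
#'   [unetBackward()] and [tinyUNetAdapter()].
#' @export
tinyUNet <- function(inputShape, nClasses = 2L, baseFilters = 8L, seed = 1L) {
  H <- inputShape[1]; W <- inputShape[2]
  if (H %% 2L || W %% 2L) stop("inputShape must have even dimensions")
  Fb <- as.integer(baseFilters)
  C <- as.integer(nClasses)
  params <- .withSeed(seed, list(
    W1 = .xavier(9, 9 * Fb, 9, Fb),             b1 = numeric(Fb),
    W2 = .xavier(9 * Fb, 9 * Fb, 9 * Fb, Fb),   b2 = numeric(Fb),
    W3 = .xavier(9 * Fb, 18 * Fb, 9 * Fb, 2 * Fb), b3 = numeric(2 * Fb),
    W4 = .xavier(27 * Fb, 9 * Fb, 27 * Fb, Fb), b4 = numeric(Fb),
    W5 = .xavier(Fb, C, Fb, C),                 b5 = numeric(C)))
  list(params = params,
       H = H, W = W, C = C, Fb = Fb,
       idxFull = .convIndex3(H, W),
       idxHalf = .convIndex3(H %/% 2L, W %/% 2L),
       poolIdx = .poolIndex2(H, W),
       upIdx = .upIndex2(H, W))
}

.convFwd <- function(x, idx, Wt, b) {
  X <- .im2col(x, idx)
  list(X = X, y = sweep(X %*% Wt, 2, b, `+`))
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the tiny U-Net
#'
#' @param model a model from [tinyUNet()].
#' @param image numeric `H x W` matrix (z-score normalised input).
#' @param keepCache keep intermediate activations for [unetBackward()].
#' @return `list(p, cache)`: `p` is the `H x W x C` probability array.
#' @export
unetForward <- function(model, image, keepCache = FALSE) {
  p <- model$params
  N <- model$H * model$W
  x0 <- matrix(as.vector(image), N, 1)
  c1 <- .convFwd(x0, model$idxFull, p$W1, p$b1); a1 <- pmax(c1$y, 0)
  c2 <- .convFwd(a1, model$idxFull, p$W2, p$b2); a2 <- pmax(c2$y, 0)
  ## 2x2 maxpool
  pi <- model$poolIdx
  m1 <- pmax(a2[pi[, 1], , drop = FALSE], a2[pi[, 2], , drop = FALSE])
  m2 <- pmax(a2[pi[, 3], , drop = FALSE], a2[pi[, 4], , drop = FALSE])
  pooled <- pmax(m1, m2)
  ## argmax winners per channel, for gradient routing in the backward pass
  win <- matrix(0L, nrow(pi), ncol(pooled))
  for (cidx in seq_len(ncol(pooled))) {
    vals <- cbind(a2[pi[, 1], cidx], a2[pi[, 2], cidx],
                  a2[pi[, 3], cidx], a2[pi[, 4], cidx])
    win[, cidx] <- pi[cbind(seq_len(nrow(pi)), max.col(vals, ties.method = "first"))]
  }
  c3 <- .convFwd(pooled, model$idxHalf, p$W3, p$b3); a3 <- pmax(c3$y, 0)
  up <- a3[model$upIdx, , drop = FALSE]
  cat4 <- cbind(a2, up)
  c4 <- .convFwd(cat4, model$idxFull, p$W4, p$b4); a4 <- pmax(c4$y, 0)
  logits <- sweep(a4 %*% p$W5, 2, p$b5, `+`)
  prob <- .softmaxRows(logits)
  cache <- NULL
  if (keepCache)
    cache <- list(X1 = c1$X, y1 = c1$y, X2 = c2$X, y2 = c2$y, a2 = a2,
                  win = win, X3 = c3$X, y3 = c3$y, X4 = c4$X, y4 = c4$y,
                  a4 = a4, prob = prob)
  list(p = array(prob, dim = c(model$H, model$W, model$C)), cache = cache)
}

#' Backward pass of the tiny U-Net
#'
#' Backpropagates a logit-space gradient (`N x C` pixel matrix, e.g. from
#' [softmaxBackward()]) through the network and returns parameter
#' gradients.
#'
#' @param model a model from [tinyUNet()].
#' @param cache the cache returned by [unetForward()] with
#'   `keepCache = TRUE`.
#' @param dLogits numeric `(H*W) x C` matrix of logit gradients.
#' @return Named list of gradients matching `model$params`.
#' @export
unetBackward <- function(model, cache, dLogits) {
  p <- model$params
  N <- model$H * model$W
  Nh <- N %/% 4L
  gW5 <- t(cache$a4) %*% dLogits
  gb5 <- colSums(dLogits)
  da4 <- dLogits %*% t(p$W5)
  dy4 <- da4 * (cache$y4 > 0)
  gW4 <- t(cache$X4) %*% dy4
  gb4 <- colSums(dy4)
  dX4 <- dy4 %*% t(p$W4)
  dcat <- .col2im(dX4, model$idxFull, N, 3L * model$Fb)
  da2skip <- dcat[, seq_len(model$Fb), drop = FALSE]
  dup <- dcat[, model$Fb + seq_len(2L * model$Fb), drop = FALSE]
  da3 <- rowsum(dup, model$upIdx)
  dy3 <- da3 * (cache$y3 > 0)
  gW3 <- t(cache$X3) %*% dy3
  gb3 <- colSums(dy3)
  dX3 <- dy3 %*% t(p$W3)
  dpooled <- .col2im(dX3, model$idxHalf, Nh, model$Fb)
  ## route pooled gradients to the argmax winners
  da2pool <- matrix(0, N, model$Fb)
  for (cidx in seq_len(model$Fb)) {
    da2pool[cache$win[, cidx], cidx] <- dpooled[, cidx]
  }
  da2 <- da2skip + da2pool
  dy2 <- da2 * (cache$y2 > 0)
  gW2 <- t(cache$X2) %*% dy2
  gb2 <- colSums(dy2)
  dX2 <- dy2 %*% t(p$W2)
  da1 <- .col2im(dX2, model$idxFull, N, model$Fb)
  dy1 <- da1 * (cache$y1 > 0)
  gW1 <- t(cache$X1) %*% dy1
  gb1 <- colSums(dy1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
}

#' Adapter wrapping the tiny U-Net for the training harness
#'
#' Satisfies the harness adapter contract: `$predict(image)` returns a
#' probability array, `$step(image, onehot, lossName, cfg, lr)` performs
#' one SGD update through the named registered loss (analytic probability
#' gradient chained through the softmax) and returns the loss value, and
#' `$lossOn(image, onehot, lossName, cfg)` evaluates without updating.
#'
#' @param inputShape `c(H, W)`.
#' @param nClasses number of classes.
#' @param baseFilters encoder width; default 8.
#' @param seed initialisation seed.
#' @return List of closures sharing one mutable model.
#' @export
tinyUNetAdapter <- function(inputShape, nClasses = 2L, baseFilters = 8L,
                            seed = 1L) {
  env <- new.env(parent = emptyenv())
  env$model <- tinyUNet(inputShape, nClasses, baseFilters, seed)
  lossEval <- function(image, onehot, lossName, cfg, update, lr) {
    fwd <- unetForward(env$model, image, keepCache = update)
    Y <- .pixelMatrix(.onehotArray(onehot))
    fn <- .lookupLoss(lossName)
    P <- .pixelMatrix(fwd$p)
    res <- fn(P, Y, cfg, update)
    if (!is.finite(res$value))
      stop(sprintf("non-finite loss (%s) during training: aborting; last value %s",
                   lossName, format(res$value)))
    if (update) {
      dLogits <- .pixelMatrix(softmaxBackward(fwd$p, array(res$grad, dim = dim(fwd$p))))
      grads <- unetBackward(env$model, fwd$cache, dLogits)
      for (nm in names(grads))
        env$model$params[[nm]] <- env$model$params[[nm]] - lr * grads[[nm]]
    }
    res$value
  }
  list(
    predict = function(image) unetForward(env$model, image)$p,
    step = function(image, onehot, lossName, cfg, lr)
      lossEval(image, onehot, lossName, cfg, TRUE, lr),
    lossOn = function(image, onehot, lossName, cfg)
      lossEval(image, onehot, lossName, cfg, FALSE, 0),
    getModel = function() env$model
  )
}
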