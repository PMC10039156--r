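## Core array plumbing: one-hot encoding, argmax decoding, soft-confusion
## aggregation. Everything flattens the spatial axes to a pixel dimension so
## 2-D and 3-D grids share one code path.

.asNumericArray <- function(v) {
  if (is.null(dim(v))) stop("expected an array, got a vector")
  storage.mode(v) <- "double"
  v
}

## (spatial..., C) array -> N x C matrix of per-pixel class vectors.
## Column-major layout makes each class channel contiguous, so this is a
## plain reshape.
.pixelMatrix <- function(v) {
  d <- dim(v)
  matrix(v, ncol = d[length(d)])
}

.spatialDim <- function(v) {
  d <- dim(v)
  d[-length(d)]
}

.sumOverClasses <- function(v) {
  d <- dim(v)
  array(rowSums(.pixelMatrix(v)), dim = d[-length(d)])
}

.expandOverClasses <- function(s, d) {
  array(rep(as.vector(s), d[length(d)]), dim = d)
}

## Zero-based argmax over the class axis; ties go to the lowest class index.
.argmaxMatrix <- function(P) max.col(P, ties.method = "first") - 1L

.checkSameShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s have dims (%s) vs (%s)", what,
                 paste(dim(a), collapse = ","), paste(dim(b), collapse = ",")))
  invisible(TRUE)
}

## Accept either the S4 wrapper or a bare array for every user-facing entry
## point; heavy numerics run on plain arrays.
.probArray <- function(p) {
  if (is(p, "ProbabilityMap")) p@values else .asNumericArray(p)
}
.maskValues <- function(m) {
  if (is(m, "LabelMask")) m@values else m
}
.onehotArray <- function(y) {
  if (is(y, "OneHotMask")) y@values
  else if (is(y, "LabelMask")) oneHotEncode(y)@values
  else .asNumericArray(y)
}

#' One-hot encode a label mask
#'
#' Expands an integer label mask over a 2-D or 3-D grid into a binary
#' indicator array with the class axis last, so that channel `c + 1` marks
#' the pixels carrying class `c`. Per-pixel argmax of the result recovers
#' the input exactly.
#'
#' @param mask a [LabelMask-class] or integer array of zero-based labels.
#' @param nClasses number of classes `C`; every label must be `< C`.
#'   Defaults to the mask's own class count.
#' @return A [OneHotMask-class] over (spatial..., `nClasses`).
#' @examples
#' m <- LabelMask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
#' values(oneHotEncode(m))
#' @export
oneHotEncode <- function(mask, nClasses = NULL) {
  v <- .maskValues(mask)
  if (is.null(dim(v))) stop("mask must be an array of rank 2 or 3")
  if (is.null(nClasses))
    nClasses <- if (is(mask, "LabelMask")) nClasses(mask) else max(2, max(v) + 1)
  nClasses <- as.integer(nClasses)
  if (any(v != round(v))) stop("mask labels must be integers")
  if (max(v) >= nClasses)
    stop(sprintf("invalid label %d: labels must be < nClasses = %d",
                 max(v), nClasses))
  if (min(v) < 0) stop(sprintf("invalid label %d: labels must be >= 0", min(v)))
  n <- length(v)
  out <- numeric(n * nClasses)
  out[seq_len(n) + n * as.vector(v)] <- 1
  new("OneHotMask", values = array(out, dim = c(dim(v), nClasses)))
}

#' Decode a probability map or one-hot mask to hard labels
#'
#' Per-pixel argmax over the class axis; ties are resolved towards the
#' lowest class index.
#'
#' @param p a [ProbabilityMap-class], [OneHotMask-class] or array with the
#'   class axis last.
#' @return A [LabelMask-class] of zero-based labels.
#' @export
decodeLabels <- function(p) {
  v <- if (is(p, "ProbabilityMap") || is(p, "OneHotMask")) p@values else .asNumericArray(p)
  d <- dim(v)
  lab <- array(.argmaxMatrix(.pixelMatrix(v)), dim = d[-length(d)])
  LabelMask(lab, nClasses = d[length(d)])
}

## x^gamma with the continuous extension 0^gamma := 0 for gamma > 0.
.powSafe <- function(x, gamma) {
  if (gamma == 1) return(x)
  out <- x^gamma
  out[x == 0] <- 0
  out
}

#' Soft and hard confusion aggregates per class
#'
#' For each class `c`, accumulates over pixels the soft true-positive mass
#' `sum(p0 * y0)`, the exponentiated soft errors `sum((p0 * y1)^gamma)` and
#' `sum((p1 * y0)^gamma)` — where `p0` is the predicted probability of class
#' `c`, `p1 = 1 - p0`, and `y0`/`y1` indicate ground-truth membership and
#' non-membership — together with hard TP/FP/FN counts taken from the
#' argmax-binarised prediction. These sums are the building blocks of the
#' whole Dice/Tversky loss family; the exponent `gamma > 1` is what turns a
#' plain Dice loss into its overconfidence-penalising "++" form.
#'
#' @param p a [ProbabilityMap-class] or probability array.
#' @param y a [OneHotMask-class], [LabelMask-class] or one-hot array of the
#'   same shape.
#' @param gamma positive exponent applied to the per-pixel FP/FN products.
#' @return A [ConfusionTerms-class] object.
#' @examples
#' y <- oneHotEncode(LabelMask(matrix(c(1L, 1L, 0L, 0L), 1, 4)))
#' p <- array(c(0, 0.5, 0.5, 1, 1, 0.5, 0.5, 0), dim = c(1, 4, 2))
#' confusionTerms(p, y, gamma = 2)
#' @export
confusionTerms <- function(p, y, gamma = 1) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  pv <- .probArray(p)
  yv <- .onehotArray(y)
  .checkSameShape(pv, yv, "probability map and one-hot mask")
  P <- .pixelMatrix(pv)
  Y <- .pixelMatrix(yv)
  C <- ncol(P)
  tpSoft <- colSums(P * Y)
  fpSoft <- colSums(.powSafe(P * (1 - Y), gamma))
  fnSoft <- colSums(.powSafe((1 - P) * Y, gamma))
  predLab <- .argmaxMatrix(P)
  trueLab <- .argmaxMatrix(Y)
  tpHard <- fpHard <- fnHard <- numeric(C)
  for (c in seq_len(C)) {
    predC <- predLab == (c - 1L)
    trueC <- trueLab == (c - 1L)
    tpHard[c] <- sum(predC & trueC)
    fpHard[c] <- sum(predC & !trueC)
    fnHard[c] <- sum(!predC & trueC)
  }
  new("ConfusionTerms", tpSoft = tpSoft, fpSoft = fpSoft, fnSoft = fnSoft,
      tpHard = tpHard, fpHard = fpHard, fnHard = fnHard,
      gamma = gamma, nPixels = nrow(P), nClasses = as.integer(C))
}
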