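## Loss family. Every loss has a reference (pure array) forward pass and an
## analytic gradient with respect to the raw probability entries; the two are
## cross-checked against a central finite-difference oracle in the test
## suite. Region losses are parameterised by the "++" exponent gammaPP, which
## exponentiates the per-pixel soft FP/FN products before summation, so that
## each original loss is recovered exactly at gammaPP = 1.

.CLIP <- 1e-7

.clipProb <- function(x) pmin(pmax(x, .CLIP), 1 - .CLIP)

## derivative of base^g w.r.t. base, with the 0^g := 0 continuous extension
.powDeriv <- function(base, g) {
  if (g == 1) return(array(1, dim = dim(base)))
  b <- if (g < 1) pmax(base, 1e-12) else base
  out <- g * b^(g - 1)
  if (g > 1) out[base == 0] <- 0
  out
}

## class channels entering region-loss sums/averages
.includedClasses <- function(C, includeBackground) {
  if (includeBackground) seq_len(C) else seq(2L, C)
}

.checkGammaPP <- function(gammaPP) {
  if (length(gammaPP) != 1 || !is.finite(gammaPP) || gammaPP <= 0)
    stop("gammaPP must be a single positive number")
  if (gammaPP < 1)
    warning(sprintf("gammaPP = %g < 1: permitted for grid searches, but values >= 1 are the intended range", gammaPP))
  invisible(gammaPP)
}

.prepPY <- function(p, y) {
  pv <- .probArray(p)
  yv <- .onehotArray(y)
  .checkSameShape(pv, yv, "probability map and one-hot mask")
  list(P = .pixelMatrix(pv), Y = .pixelMatrix(yv), dim = dim(pv))
}

.asLossValue <- function(value, perClass = NULL) {
  if (!is.null(perClass)) attr(value, "perClass") <- perClass
  value
}

## ---- cross entropy --------------------------------------------------------

.ceCore <- function(P, Y, grad = FALSE) {
  N <- nrow(P)
  Pc <- .clipProb(P)
  value <- -sum(Y * log(Pc)) / N
  g <- NULL
  if (grad) {
    inside <- P > .CLIP & P < 1 - .CLIP
    g <- -(Y / Pc) * inside / N
  }
  list(value = value, grad = g)
}

#' Cross-entropy loss
#'
#' Mean over pixels of the negative log probability assigned to the true
#' class: `-(1/N) sum_i sum_c y * log(p)`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]` before the log. Identical in form to the negative log
#' likelihood used as a calibration metric.
#'
#' @param p a [ProbabilityMap-class] or probability array, class axis last.
#' @param y a [OneHotMask-class], [LabelMask-class] or one-hot array.
#' @return Non-negative numeric scalar.
#' @examples
#' y <- oneHotEncode(LabelMask(matrix(c(0L, 1L), 1, 2)))
#' p <- array(c(0.9, 0.4, 0.1, 0.6), dim = c(1, 2, 2))
#' ceLoss(p, y)  # -(log(0.9) + log(0.6)) / 2
#' @export
ceLoss <- function(p, y) {
  d <- .prepPY(p, y)
  .asLossValue(.ceCore(d$P, d$Y)$value)
}

## ---- focal ----------------------------------------------------------------

.focalCore <- function(P, Y, alpha, gamma, grad = FALSE) {
  N <- nrow(P); C <- ncol(P)
  if (length(alpha) == 1L) alpha <- rep(alpha, C)
  if (length(alpha) != C)
    stop(sprintf("focal alpha must have length 1 or C = %d, got %d", C, length(alpha)))
  trueLab <- .argmaxMatrix(Y)
  idx <- cbind(seq_len(N), trueLab + 1L)
  pt <- P[idx]
  ptc <- .clipProb(pt)
  a <- alpha[trueLab + 1L]
  value <- sum(a * (1 - pt)^gamma * (-log(ptc))) / N
  g <- NULL
  if (grad) {
    inside <- pt > .CLIP & pt < 1 - .CLIP
    base <- if (gamma < 1 && gamma != 0) pmax(1 - pt, 1e-12) else (1 - pt)
    dmod <- if (gamma == 0) 0 else gamma * base^(gamma - 1) * log(ptc)
    dlog <- -(1 - pt)^gamma / ptc * inside
    g <- matrix(0, N, C)
    g[idx] <- a * (dmod + dlog) / N
  }
  list(value = value, grad = g)
}

#' Focal loss
#'
#' Cross entropy with a per-pixel modulating factor `(1 - p_t)^gamma` that
#' down-weights easy (confident, correct) pixels, and a per-class weight
#' vector `alpha`. At `gamma = 0` and `alpha = 1` it reduces exactly to the
#' cross-entropy loss.
#'
#' @inheritParams ceLoss
#' @param alpha per-class weight vector (scalar recycled); default 0.5.
#' @param gamma focusing exponent `>= 0`; default 2.
#' @param cfg a [LossConfig-class] supplying defaults.
#' @return Non-negative numeric scalar.
#' @export
focalLoss <- function(p, y, alpha = cfg@focalAlpha, gamma = cfg@focalGamma,
                      cfg = LossConfig()) {
  if (gamma < 0) stop("focal gamma must be >= 0")
  d <- .prepPY(p, y)
  .asLossValue(.focalCore(d$P, d$Y, alpha, gamma)$value)
}

## ---- soft Dice (overlap-form) ---------------------------------------------

.dscCore <- function(P, Y, eps, includeBackground, grad = FALSE) {
  C <- ncol(P)
  cls <- .includedClasses(C, includeBackground)
  if (length(cls) == 0) stop("no classes left after background exclusion")
  A <- 2 * colSums(P * Y) + eps
  B <- colSums(P) + colSums(Y) + eps
  ratio <- A / B
  perClass <- 1 - ratio
  value <- 1 - mean(ratio[cls])
  g <- NULL
  if (grad) {
    m <- length(cls)
    g <- matrix(0, nrow(P), C)
    for (c in cls)
      g[, c] <- -((2 * Y[, c]) * B[c] - A[c]) / (B[c]^2) / m
  }
  list(value = value, grad = g, perClass = perClass)
}

#' Soft Dice loss (overlap form)
#'
#' One minus the class-averaged soft Dice score
#' `2 * sum(p y) / (sum(p) + sum(y))`, computed directly from the overlap
#' form of the Dice coefficient. Algebraically identical to
#' [dscppLoss()] at `gammaPP = 1` (which works from the soft confusion
#' sums instead); the two share only the smoothing constant, making them
#' independent implementations used to cross-check each other.
#'
#' @inheritParams focalLoss
#' @return Numeric scalar in `[0, 1]`, with a `"perClass"` attribute.
#' @export
dscLoss <- function(p, y, cfg = LossConfig()) {
  d <- .prepPY(p, y)
  r <- .dscCore(d$P, d$Y, cfg@smoothEps, cfg@includeBackground)
  .asLossValue(r$value, r$perClass)
}

## ---- DSC++ ----------------------------------------------------------------

.softSums <- function(P, Y, gammaPP) {
  list(tp = colSums(P * Y),
       fp = colSums(.powSafe(P * (1 - Y), gammaPP)),
       fn = colSums(.powSafe((1 - P) * Y, gammaPP)))
}

## per-entry derivatives of the exponentiated FP/FN sums w.r.t. P
.softSumDerivs <- function(P, Y, gammaPP) {
  list(dfp = .powDeriv(P * (1 - Y), gammaPP) * (1 - Y),
       dfn = -.powDeriv((1 - P) * Y, gammaPP) * Y)
}

.dscppCore <- function(P, Y, gammaPP, eps, includeBackground, grad = FALSE) {
  C <- ncol(P)
  cls <- .includedClasses(C, includeBackground)
  if (length(cls) == 0) stop("no classes left after background exclusion")
  s <- .softSums(P, Y, gammaPP)
  A <- 2 * s$tp + eps
  B <- 2 * s$tp + s$fp + s$fn + eps
  ratio <- A / B
  perClass <- 1 - ratio
  value <- 1 - mean(ratio[cls])
  g <- NULL
  if (grad) {
    m <- length(cls)
    dv <- .softSumDerivs(P, Y, gammaPP)
    g <- matrix(0, nrow(P), C)
    for (c in cls) {
      dA <- 2 * Y[, c]
      dB <- dA + dv$dfp[, c] + dv$dfn[, c]
      g[, c] <- -(dA * B[c] - A[c] * dB) / (B[c]^2) / m
    }
  }
  list(value = value, grad = g, perClass = perClass)
}

#' DSC++ loss
#'
#' The calibration-aware extension of the soft Dice loss. Writing the Dice
#' loss in terms of the per-class soft confusion sums, the focal exponent
#' `gammaPP` is applied directly to the per-pixel FP and FN probability
#' products:
#' \deqn{L = 1 - \frac{1}{C}\sum_c
#'   \frac{2\sum_i p_0 y_0}
#'        {2\sum_i p_0 y_0 + \sum_i (p_0 y_1)^\gamma + \sum_i (p_1 y_0)^\gamma}}
#' At `gammaPP = 1` this is exactly the Dice loss; for `gammaPP > 1`
#' confident errors (products near 1) keep their full penalty while
#' low-confidence errors are discounted, so the optimum no longer pushes
#' probabilities to the extremes in uncertain regions.
#'
#' @inheritParams focalLoss
#' @param gammaPP focal exponent on the soft FP/FN products; default 2.
#'   Values in `[0.5, 1)` are accepted for grid searches with a warning.
#' @return Numeric scalar with a `"perClass"` attribute.
#' @examples
#' y <- oneHotEncode(LabelMask(matrix(c(1L, 1L, 0L, 0L), 1, 4)))
#' pf <- c(1, 0.5, 0.5, 0)
#' p <- array(c(1 - pf, pf), dim = c(1, 4, 2))
#' dscppLoss(p, y, gammaPP = 2, cfg = LossConfig(includeBackground = FALSE))
#' @export
dscppLoss <- function(p, y, gammaPP = cfg@gammaPP, cfg = LossConfig()) {
  .checkGammaPP(gammaPP)
  d <- .prepPY(p, y)
  r <- .dscppCore(d$P, d$Y, gammaPP, cfg@smoothEps, cfg@includeBackground)
  .asLossValue(r$value, r$perClass)
}

## ---- Tversky family -------------------------------------------------------

.tverskyIndex <- function(P, Y, alpha, beta, gammaPP, eps, double = FALSE,
                          grad = FALSE) {
  s <- .softSums(P, Y, gammaPP)
  k <- if (double) 2 else 1
  A <- k * s$tp + eps
  B <- k * (s$tp + alpha * s$fp + beta * s$fn) + eps
  TI <- A / B
  dTI <- NULL
  if (grad) {
    dv <- .softSumDerivs(P, Y, gammaPP)
    C <- ncol(P)
    dTI <- matrix(0, nrow(P), C)
    for (c in seq_len(C)) {
      dA <- k * Y[, c]
      dB <- k * (Y[, c] + alpha * dv$dfp[, c] + beta * dv$dfn[, c])
      dTI[, c] <- (dA * B[c] - A[c] * dB) / (B[c]^2)
    }
  }
  list(TI = TI, dTI = dTI)
}

.tverskyCore <- function(P, Y, alpha, beta, gammaPP, eps, includeBackground,
                         average = FALSE, double = FALSE, grad = FALSE) {
  if (alpha == 0 && beta == 0)
    stop("degenerate parameters: alpha and beta cannot both be zero")
  C <- ncol(P)
  cls <- .includedClasses(C, includeBackground)
  ti <- .tverskyIndex(P, Y, alpha, beta, gammaPP, eps, double, grad)
  perClass <- 1 - ti$TI
  total <- if (average) mean(perClass[cls]) else sum(perClass[cls])
  g <- NULL
  if (grad) {
    scale <- if (average) 1 / length(cls) else 1
    g <- matrix(0, nrow(P), C)
    g[, cls] <- -ti$dTI[, cls] * scale
  }
  list(value = total, grad = g, perClass = perClass)
}

#' Tversky loss
#'
#' Region loss `sum_c (1 - TI_c)` built on the Tversky index
#' `TI = tp / (tp + alpha * fp + beta * fn)`, which generalises the Dice
#' score by weighting false positives and false negatives asymmetrically
#' (`alpha` on FP, `beta` on FN; `beta > alpha` trades precision for
#' recall). With `gammaPP > 1` the soft FP/FN products are exponentiated as
#' in [dscppLoss()], giving the "++" variant. As printed the loss sums over
#' classes, so its range is `[0, C]`.
#'
#' @inheritParams dscppLoss
#' @param alpha,beta FP and FN weights; defaults 0.3 and 0.7.
#' @param average average over classes instead of summing (default `FALSE`,
#'   the summed convention).
#' @param double use the doubled-numerator convention
#'   `(2 tp) / (2 tp + 2 alpha fp + 2 beta fn)`; at `alpha = beta = 0.5`
#'   this makes the index coincide exactly (including smoothing) with the
#'   Dice score.
#' @return Numeric scalar with a `"perClass"` attribute.
#' @export
tverskyLoss <- function(p, y, alpha = cfg@tverskyAlpha, beta = cfg@tverskyBeta,
                        gammaPP = 1, cfg = LossConfig(), average = FALSE,
                        double = FALSE) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  .checkGammaPP(gammaPP)
  d <- .prepPY(p, y)
  r <- .tverskyCore(d$P, d$Y, alpha, beta, gammaPP, cfg@smoothEps,
                    cfg@includeBackground, average, double)
  .asLossValue(r$value, r$perClass)
}

.focalTverskyCore <- function(P, Y, alpha, beta, ftGamma, gammaPP, eps,
                              includeBackground, grad = FALSE) {
  if (alpha == 0 && beta == 0)
    stop("degenerate parameters: alpha and beta cannot both be zero")
  C <- ncol(P)
  cls <- .includedClasses(C, includeBackground)
  ti <- .tverskyIndex(P, Y, alpha, beta, gammaPP, eps, grad = grad)
  expo <- 1 / ftGamma
  perClass <- (1 - ti$TI)^expo
  value <- sum(perClass[cls])
  g <- NULL
  if (grad) {
    g <- matrix(0, nrow(P), C)
    for (c in cls) {
      base <- max(1 - ti$TI[c], 1e-12)
      g[, c] <- -expo * base^(expo - 1) * ti$dTI[, c]
    }
  }
  list(value = value, grad = g, perClass = perClass)
}

#' Focal Tversky loss
#'
#' `sum_c (1 - TI_c)^(1/gamma)`: the Tversky loss with a focal exponent on
#' the per-class complement, so poorly-overlapping classes contribute
#' disproportionately. `gamma = 1` recovers [tverskyLoss()] exactly.
#'
#' @inheritParams tverskyLoss
#' @param ftGamma focal exponent `> 0`; the loss uses `1/ftGamma`.
#'   Default 4/3.
#' @return Numeric scalar with a `"perClass"` attribute.
#' @export
focalTverskyLoss <- function(p, y, alpha = cfg@tverskyAlpha,
                             beta = cfg@tverskyBeta, ftGamma = cfg@ftGamma,
                             gammaPP = 1, cfg = LossConfig()) {
  if (ftGamma <= 0) stop("ftGamma must be > 0")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  .checkGammaPP(gammaPP)
  d <- .prepPY(p, y)
  r <- .focalTverskyCore(d$P, d$Y, alpha, beta, ftGamma, gammaPP,
                         cfg@smoothEps, cfg@includeBackground)
  .asLossValue(r$value, r$perClass)
}

## ---- Combo ----------------------------------------------------------------

## Modified CE of the Combo loss, written on the foreground channel(s):
## -(1/N) sum_i [beta * y * ln p + (1 - beta) * (1 - y) * ln(1 - p)],
## averaged over foreground channels when C > 2.
.mceCore <- function(P, Y, beta, grad = FALSE) {
  N <- nrow(P); C <- ncol(P)
  fg <- seq(2L, C)
  K <- length(fg)
  Pf <- .clipProb(P[, fg, drop = FALSE])
  Yf <- Y[, fg, drop = FALSE]
  value <- -sum(beta * Yf * log(Pf) + (1 - beta) * (1 - Yf) * log(1 - Pf)) / (N * K)
  g <- NULL
  if (grad) {
    raw <- P[, fg, drop = FALSE]
    inside <- raw > .CLIP & raw < 1 - .CLIP
    g <- matrix(0, N, C)
    g[, fg] <- (-beta * Yf / Pf + (1 - beta) * (1 - Yf) / (1 - Pf)) * inside / (N * K)
  }
  list(value = value, grad = g)
}

.comboCore <- function(P, Y, comboAlpha, comboBeta, gammaPP, eps,
                       includeBackground, grad = FALSE) {
  mce <- .mceCore(P, Y, comboBeta, grad)
  dpp <- .dscppCore(P, Y, gammaPP, eps, includeBackground, grad)
  dscScore <- 1 - dpp$value
  value <- comboAlpha * mce$value - (1 - comboAlpha) * dscScore
  g <- NULL
  if (grad) g <- comboAlpha * mce$grad + (1 - comboAlpha) * dpp$grad
  list(value = value, grad = g)
}

#' Combo loss
#'
#' Weighted sum of a modified cross entropy and the (negated) soft Dice
#' score: `alpha * mCE - (1 - alpha) * DSC`. The modified CE applies `beta`
#' to the positive-class log term and `1 - beta` to the negative-class term
#' on the foreground channel, so `beta` trades the penalty on false
#' negatives against false positives. With `gammaPP > 1` the Dice component
#' is replaced by the DSC++ score, giving the "++" variant. Because the
#' Dice score enters negated, the loss can be negative (down to
#' `-(1 - alpha)` for a perfect prediction).
#'
#' @inheritParams dscppLoss
#' @param comboAlpha weight on the CE term (`1 - comboAlpha` on the Dice
#'   score); default 0.5.
#' @param comboBeta positive-class weight inside the modified CE;
#'   default 0.5.
#' @return Numeric scalar (may be negative).
#' @export
comboLoss <- function(p, y, comboAlpha = cfg@comboAlpha,
                      comboBeta = cfg@comboBeta, gammaPP = 1,
                      cfg = LossConfig()) {
  if (comboAlpha < 0 || comboAlpha > 1 || comboBeta < 0 || comboBeta > 1)
    stop("comboAlpha and comboBeta must lie in [0, 1]")
  .checkGammaPP(gammaPP)
  d <- .prepPY(p, y)
  .asLossValue(.comboCore(d$P, d$Y, comboAlpha, comboBeta, gammaPP,
                          cfg@smoothEps, cfg@includeBackground)$value)
}

## ---- Unified Focal --------------------------------------------------------

.resolveRareClasses <- function(rareClass, C) {
  if (length(rareClass) == 1 && is.na(rareClass)) return(seq(2L, C))
  if (any(rareClass != round(rareClass)) || any(rareClass < 0) ||
      any(rareClass > C - 1))
    stop(sprintf("rareClass must contain class ids in [0, %d]", C - 1))
  as.integer(rareClass) + 1L
}

.asymFocalCore <- function(P, Y, delta, ufGamma, rareCols, grad = FALSE) {
  N <- nrow(P); C <- ncol(P)
  trueLab <- .argmaxMatrix(Y)
  idx <- cbind(seq_len(N), trueLab + 1L)
  pt <- P[idx]
  ptc <- .clipProb(pt)
  isRare <- (trueLab + 1L) %in% rareCols
  value <- (delta * sum(-log(ptc[isRare])) +
            (1 - delta) * sum((1 - pt[!isRare])^ufGamma * (-log(ptc[!isRare])))) / N
  g <- NULL
  if (grad) {
    inside <- pt > .CLIP & pt < 1 - .CLIP
    dpt <- numeric(N)
    dpt[isRare] <- -delta / ptc[isRare] * inside[isRare]
    pn <- pt[!isRare]
    dpt[!isRare] <- (1 - delta) *
      (ufGamma * pmax(1 - pn, 1e-12)^(ufGamma - 1) * log(.clipProb(pn)) -
       (1 - pn)^ufGamma / .clipProb(pn) * inside[!isRare])
    g <- matrix(0, N, C)
    g[idx] <- dpt / N
  }
  list(value = value, grad = g)
}

.asymFocalTverskyCore <- function(P, Y, delta, ufGamma, gammaPP, eps,
                                  includeBackground, rareCols, grad = FALSE) {
  C <- ncol(P)
  cls <- .includedClasses(C, includeBackground)
  ti <- .tverskyIndex(P, Y, alpha = 1 - delta, beta = delta, gammaPP, eps,
                      grad = grad)
  comp <- 1 - ti$TI
  expo <- ifelse(seq_len(C) %in% rareCols, 1 - ufGamma, 1)
  perClass <- comp^expo
  value <- sum(perClass[cls])
  g <- NULL
  if (grad) {
    g <- matrix(0, nrow(P), C)
    for (c in cls) {
      base <- max(comp[c], 1e-12)
      g[, c] <- -expo[c] * base^(expo[c] - 1) * ti$dTI[, c]
    }
  }
  list(value = value, grad = g, perClass = perClass)
}

.unifiedFocalCore <- function(P, Y, ufLambda, ufDelta, ufGamma, gammaPP, eps,
                              includeBackground, rareClass, grad = FALSE) {
  rareCols <- .resolveRareClasses(rareClass, ncol(P))
  af <- .asymFocalCore(P, Y, ufDelta, ufGamma, rareCols, grad)
  aft <- .asymFocalTverskyCore(P, Y, ufDelta, ufGamma, gammaPP, eps,
                               includeBackground, rareCols, grad)
  value <- ufLambda * af$value + (1 - ufLambda) * aft$value
  g <- NULL
  if (grad) g <- ufLambda * af$grad + (1 - ufLambda) * aft$grad
  list(value = value, grad = g)
}

#' Unified Focal loss
#'
#' Weighted sum `lambda * L_AF + (1 - lambda) * L_AFT` of an asymmetric
#' focal (cross-entropy) component and an asymmetric focal Tversky
#' component, unifying the distribution- and region-based loss families.
#' The rare class(es) `r` are exempted from focal down-weighting: in the CE
#' component, rare-class pixels contribute a plain `delta`-weighted log
#' term while other pixels get the `(1 - delta)`-weighted focal term; in
#' the Tversky component (FP weight `1 - delta`, FN weight `delta`) the
#' rare class is enhanced by the exponent `1 - gamma`. With `gammaPP > 1`
#' the soft FP/FN sums inside the Tversky index are exponentiated, giving
#' the "++" variant.
#'
#' @inheritParams dscppLoss
#' @param ufLambda mixing weight in `[0, 1]`; default 0.5.
#' @param ufDelta asymmetry weight in `[0, 1]`; default 0.6.
#' @param ufGamma focal parameter in `(0, 1)`; default 0.5.
#' @param rareClass zero-based rare class id(s); `NA` (default) means all
#'   foreground classes.
#' @return Numeric scalar.
#' @export
unifiedFocalLoss <- function(p, y, ufLambda = cfg@ufLambda,
                             ufDelta = cfg@ufDelta, ufGamma = cfg@ufGamma,
                             gammaPP = 1, rareClass = cfg@rareClass,
                             cfg = LossConfig()) {
  if (ufLambda < 0 || ufLambda > 1 || ufDelta < 0 || ufDelta > 1)
    stop("ufLambda and ufDelta must lie in [0, 1]")
  if (ufGamma <= 0 || ufGamma >= 1)
    stop("ufGamma must lie strictly in (0, 1)")
  .checkGammaPP(gammaPP)
  d <- .prepPY(p, y)
  .asLossValue(.unifiedFocalCore(d$P, d$Y, ufLambda, ufDelta, ufGamma,
                                 gammaPP, cfg@smoothEps, cfg@includeBackground,
                                 rareClass)$value)
}

## ---- registry -------------------------------------------------------------

## Each entry evaluates value and (optionally) the gradient w.r.t. the raw
## probability entries, as an (N x C) pixel matrix. The "++" names use the
## config's gammaPP; the plain names pin gammaPP = 1.
.lossRegistry <- function() {
  list(
    "ce" = function(P, Y, cfg, grad) .ceCore(P, Y, grad),
    "focal" = function(P, Y, cfg, grad)
      .focalCore(P, Y, cfg@focalAlpha, cfg@focalGamma, grad),
    "dsc" = function(P, Y, cfg, grad)
      .dscCore(P, Y, cfg@smoothEps, cfg@includeBackground, grad),
    "dsc++" = function(P, Y, cfg, grad)
      .dscppCore(P, Y, cfg@gammaPP, cfg@smoothEps, cfg@includeBackground, grad),
    "tversky" = function(P, Y, cfg, grad)
      .tverskyCore(P, Y, cfg@tverskyAlpha, cfg@tverskyBeta, 1,
                   cfg@smoothEps, cfg@includeBackground, grad = grad),
    "tversky++" = function(P, Y, cfg, grad)
      .tverskyCore(P, Y, cfg@tverskyAlpha, cfg@tverskyBeta, cfg@gammaPP,
                   cfg@smoothEps, cfg@includeBackground, grad = grad),
    "focal_tversky" = function(P, Y, cfg, grad)
      .focalTverskyCore(P, Y, cfg@tverskyAlpha, cfg@tverskyBeta, cfg@ftGamma,
                        1, cfg@smoothEps, cfg@includeBackground, grad),
    "focal_tversky++" = function(P, Y, cfg, grad)
      .focalTverskyCore(P, Y, cfg@tverskyAlpha, cfg@tverskyBeta, cfg@ftGamma,
                        cfg@gammaPP, cfg@smoothEps, cfg@includeBackground, grad),
    "combo" = function(P, Y, cfg, grad)
      .comboCore(P, Y, cfg@comboAlpha, cfg@comboBeta, 1, cfg@smoothEps,
                 cfg@includeBackground, grad),
    "combo++" = function(P, Y, cfg, grad)
      .comboCore(P, Y, cfg@comboAlpha, cfg@comboBeta, cfg@gammaPP,
                 cfg@smoothEps, cfg@includeBackground, grad),
    "unified_focal" = function(P, Y, cfg, grad)
      .unifiedFocalCore(P, Y, cfg@ufLambda, cfg@ufDelta, cfg@ufGamma, 1,
                        cfg@smoothEps, cfg@includeBackground, cfg@rareClass, grad),
    "unified_focal++" = function(P, Y, cfg, grad)
      .unifiedFocalCore(P, Y, cfg@ufLambda, cfg@ufDelta, cfg@ufGamma,
                        cfg@gammaPP, cfg@smoothEps, cfg@includeBackground,
                        cfg@rareClass, grad)
  )
}

#' Names of all registered losses
#'
#' The "++" variants use the configured `gammaPP`; the plain names pin
#' `gammaPP = 1` so they are the original losses.
#'
#' @return Character vector of loss names accepted by [lossValue()],
#'   [lossGradient()], the training harness and the CLI.
#' @export
registeredLosses <- function() names(.lossRegistry())

.lookupLoss <- function(name) {
  reg <- .lossRegistry()
  if (!name %in% names(reg))
    stop(sprintf("unknown loss '%s'; registered: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[name]]
}

#' Evaluate a registered loss by name
#'
#' @param name one of [registeredLosses()].
#' @inheritParams focalLoss
#' @return Numeric scalar loss value.
#' @export
lossValue <- function(name, p, y, cfg = LossConfig()) {
  fn <- .lookupLoss(name)
  d <- .prepPY(p, y)
  fn(d$P, d$Y, cfg, FALSE)$value
}

#' Analytic gradient of a registered loss
#'
#' Hand-derived gradient of the loss with respect to each raw probability
#' entry (no softmax renormalisation is applied — use
#' [softmaxBackward()] to chain through a softmax). Verified against
#' [numericalGradient()] in the test suite.
#'
#' @inheritParams lossValue
#' @return Numeric array of the same shape as `p`.
#' @export
lossGradient <- function(name, p, y, cfg = LossConfig()) {
  fn <- .lookupLoss(name)
  pv <- .probArray(p)
  d <- .prepPY(p, y)
  array(fn(d$P, d$Y, cfg, TRUE)$grad, dim = dim(pv))
}

#' Finite-difference gradient oracle
#'
#' Central finite differences of a registered loss with respect to each
#' probability entry. Perturbations are applied to the raw entry without
#' renormalisation, matching the convention of [lossGradient()]. Intended
#' as a verification oracle: it is exact to `O(h^2)` but costs two loss
#' evaluations per entry.
#'
#' @inheritParams lossValue
#' @param h step size in `(0, 1e-3]`; default `1e-5`. Entries of `p`
#'   should lie in `(h, 1 - h)`.
#' @return Numeric array of the same shape as `p`.
#' @export
numericalGradient <- function(name, p, y, cfg = LossConfig(), h = 1e-5) {
  if (h <= 0 || h > 1e-3) stop("h must lie in (0, 1e-3]")
  fn <- .lookupLoss(name)
  pv <- .probArray(p)
  yv <- .onehotArray(y)
  .checkSameShape(pv, yv, "probability map and one-hot mask")
  Y <- .pixelMatrix(yv)
  P <- .pixelMatrix(pv)
  g <- numeric(length(P))
  for (j in seq_along(P)) {
    Pp <- P; Pp[j] <- P[j] + h
    Pm <- P; Pm[j] <- P[j] - h
    g[j] <- (fn(Pp, Y, cfg, FALSE)$value - fn(Pm, Y, cfg, FALSE)$value) / (2 * h)
  }
  array(g, dim = dim(pv))
}

#' Backpropagate a probability-space gradient through a softmax
#'
#' Given `p = softmax(z)` and the gradient of a loss with respect to `p`,
#' returns the gradient with respect to the logits `z`:
#' `dz_c = p_c * (dp_c - sum_j dp_j p_j)`.
#'
#' @param p probability array (class axis last).
#' @param dp gradient with respect to `p`, same shape.
#' @return Gradient with respect to the logits, same shape.
#' @export
softmaxBackward <- function(p, dp) {
  pv <- .probArray(p)
  .checkSameShape(pv, dp, "probabilities and gradient")
  P <- .pixelMatrix(pv)
  D <- .pixelMatrix(dp)
  inner <- rowSums(D * P)
  array(P * (D - inner), dim = dim(pv))
}
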