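# Fixtures built in code: random valid probability maps and masks, the
# canonical 4-pixel binary example used by the hand-derived loss values,
# and naive per-pixel loop oracles for the loss family.

# random valid probability map: softmax of scaled gaussian logits
randomProbArray <- function(dims, scale = 2) {
  C <- dims[length(dims)]
  N <- prod(dims[-length(dims)])
  Z <- matrix(stats::rnorm(N * C, sd = scale), N, C)
  P <- exp(Z - apply(Z, 1, max))
  P <- P / rowSums(P)
  array(P, dim = dims)
}

randomMaskArray <- function(spatial, nClasses) {
  array(sample(0:(nClasses - 1), prod(spatial), replace = TRUE), dim = spatial)
}

# strictly interior random map (entries in (lo, 1 - lo)), for gradient checks
interiorProbArray <- function(dims, lo = 0.05) {
  p <- randomProbArray(dims)
  C <- dims[length(dims)]
  P <- matrix(p, ncol = C)
  P <- lo + (1 - C * lo) * P          # affine squeeze keeps row sums at 1
  array(P, dim = dims)
}

# the 4-pixel binary worked example: y_fg = (1,1,0,0), p_fg = (1,.5,.5,0)
fourPixelExample <- function() {
  yfg <- c(1, 1, 0, 0)
  pfg <- c(1, 0.5, 0.5, 0)
  list(p = array(c(1 - pfg, pfg), dim = c(1, 4, 2)),
       y = oneHotEncode(LabelMask(matrix(as.integer(yfg), 1, 4))),
       mask = matrix(as.integer(yfg), 1, 4))
}

# config matching the worked examples: foreground channel only
cfgForeground <- function(...) LossConfig(includeBackground = FALSE, ...)

# ---- naive per-pixel loop oracles (independent of the vectorised code) ----

oracleSoftSums <- function(p, y, gamma) {
  d <- dim(p); C <- d[length(d)]
  P <- matrix(p, ncol = C); Y <- matrix(y, ncol = C)
  tp <- fp <- fn <- numeric(C)
  for (c in seq_len(C)) for (i in seq_len(nrow(P))) {
    tp[c] <- tp[c] + P[i, c] * Y[i, c]
    e1 <- P[i, c] * (1 - Y[i, c]); e2 <- (1 - P[i, c]) * Y[i, c]
    fp[c] <- fp[c] + if (e1 == 0) 0 else e1^gamma
    fn[c] <- fn[c] + if (e2 == 0) 0 else e2^gamma
  }
  list(tp = tp, fp = fp, fn = fn)
}

oracleDscpp <- function(p, y, gamma, eps = 1e-6, includeBackground = TRUE) {
  s <- oracleSoftSums(p, y, gamma)
  cls <- if (includeBackground) seq_along(s$tp) else seq_along(s$tp)[-1]
  1 - mean((2 * s$tp[cls] + eps) / (2 * s$tp[cls] + s$fp[cls] + s$fn[cls] + eps))
}

oracleCE <- function(p, y) {
  d <- dim(p); C <- d[length(d)]
  P <- pmin(pmax(matrix(p, ncol = C), 1e-7), 1 - 1e-7)
  Y <- matrix(y, ncol = C)
  acc <- 0
  for (i in seq_len(nrow(P))) for (c in seq_len(C))
    acc <- acc - Y[i, c] * log(P[i, c])
  acc / nrow(P)
}

oracleFocal <- function(p, y, alpha, gamma) {
  d <- dim(p); C <- d[length(d)]
  P <- matrix(p, ncol = C); Y <- matrix(y, ncol = C)
  if (length(alpha) == 1) alpha <- rep(alpha, C)
  acc <- 0
  for (i in seq_len(nrow(P))) {
    tc <- which.max(Y[i, ])
    pt <- P[i, tc]
    acc <- acc + alpha[tc] * (1 - pt)^gamma * (-log(min(max(pt, 1e-7), 1 - 1e-7)))
  }
  acc / nrow(P)
}

oracleTversky <- function(p, y, alpha, beta, gamma, eps = 1e-6,
                          includeBackground = TRUE) {
  s <- oracleSoftSums(p, y, gamma)
  cls <- if (includeBackground) seq_along(s$tp) else seq_along(s$tp)[-1]
  sum(1 - (s$tp[cls] + eps) /
        (s$tp[cls] + alpha * s$fp[cls] + beta * s$fn[cls] + eps))
}

oracleUnifiedFocal <- function(p, y, lambda, delta, gamma, gammaPP,
                               eps = 1e-6, rareCols = NULL) {
  d <- dim(p); C <- d[length(d)]
  P <- matrix(p, ncol = C); Y <- matrix(y, ncol = C)
  if (is.null(rareCols)) rareCols <- 2:C
  N <- nrow(P)
  af <- 0
  for (i in seq_len(N)) {
    tc <- which.max(Y[i, ])
    pt <- min(max(P[i, tc], 1e-7), 1 - 1e-7)
    af <- af + if (tc %in% rareCols) -delta * log(pt)
               else -(1 - delta) * (1 - P[i, tc])^gamma * log(pt)
  }
  af <- af / N
  s <- oracleSoftSums(p, y, gammaPP)
  TI <- (s$tp + eps) / (s$tp + (1 - delta) * s$fp + delta * s$fn + eps)
  aft <- sum(ifelse(seq_len(C) %in% rareCols, (1 - TI)^(1 - gamma), 1 - TI))
  lambda * af + (1 - lambda) * aft
}

# flood fill connectivity check (8-connected in 2-D)
isConnected8 <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- cur[1] + dr; c <- cur[2] + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] != 0 &&
          !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  all(seen[mask != 0])
}

oracleFocalTversky <- function(p, y, alpha, beta, ftGamma, gamma,
                               eps = 1e-6, includeBackground = TRUE) {
  s <- oracleSoftSums(p, y, gamma)
  cls <- if (includeBackground) seq_along(s$tp) else seq_along(s$tp)[-1]
  TI <- (s$tp + eps) / (s$tp + alpha * s$fp + beta * s$fn + eps)
  sum((1 - TI[cls])^(1 / ftGamma))
}

oracleCombo <- function(p, y, comboAlpha, comboBeta, gamma, eps = 1e-6) {
  d <- dim(p); C <- d[length(d)]
  P <- matrix(p, ncol = C); Y <- matrix(y, ncol = C)
  N <- nrow(P)
  clip <- function(x) min(max(x, 1e-7), 1 - 1e-7)
  mce <- 0
  for (cc in 2:C) for (i in seq_len(N)) {
    pc <- clip(P[i, cc])
    mce <- mce - (comboBeta * Y[i, cc] * log(pc) +
                  (1 - comboBeta) * (1 - Y[i, cc]) * log(1 - pc))
  }
  mce <- mce / (N * (C - 1))
  comboAlpha * mce - (1 - comboAlpha) * (1 - oracleDscpp(p, y, gamma, eps))
}
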