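# Loss family: hand-derived worked examples, identity ladder, loop oracles,
# penalty monotonicity, endpoint behaviour.

test_that("hand-derived worked examples reproduce", {
  ex <- fourPixelExample()
  cfg <- cfgForeground()
  # soft Dice on the foreground channel: 1 - 3/4
  expect_equal(dscppLoss(ex$p, ex$y, gammaPP = 1, cfg = cfg), 0.25,
               tolerance = 1e-5, ignore_attr = TRUE)
  # gamma = 2 discounts the two half-confidence errors: 1 - 3/3.5
  expect_equal(dscppLoss(ex$p, ex$y, gammaPP = 2, cfg = cfg), 1 - 3 / 3.5,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(tverskyLoss(ex$p, ex$y, 0.3, 0.7, 1, cfg = cfg), 0.25,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(tverskyLoss(ex$p, ex$y, 0.3, 0.7, 2, cfg = cfg),
               1 - 1.5 / 1.75, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(focalTverskyLoss(ex$p, ex$y, 0.3, 0.7, 4 / 3, 1, cfg = cfg),
               0.25^0.75, tolerance = 1e-5, ignore_attr = TRUE)

  y2 <- oneHotEncode(LabelMask(matrix(c(0L, 1L), 1, 2)))
  p2 <- array(c(0.9, 0.4, 0.1, 0.6), dim = c(1, 2, 2))
  expect_equal(ceLoss(p2, y2), -(log(0.9) + log(0.6)) / 2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # single pixel with p_t = 0.5, alpha = 0.5, gamma = 2
  p3 <- array(c(0.5, 0.5), dim = c(1, 1, 2))
  y3 <- oneHotEncode(LabelMask(matrix(0L, 1, 1)))
  expect_equal(focalLoss(p3, y3, alpha = 0.5, gamma = 2),
               0.5 * 0.25 * log(2), tolerance = 1e-9, ignore_attr = TRUE)

  # binary uniform p = 0.5 everywhere: CE is ln 2
  pu <- array(0.5, dim = c(3, 3, 2))
  yu <- oneHotEncode(randomMaskArray(c(3, 3), 2), 2)
  expect_equal(ceLoss(pu, yu), log(2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("perfect and anti-perfect predictions hit the documented extremes", {
  set.seed(7)
  m <- randomMaskArray(c(6, 6), 2)
  y <- oneHotEncode(m, 2)
  p <- values(y)
  cfg <- LossConfig()
  expect_lt(ceLoss(p, y), 1.2e-7)          # clip-floor effect only
  expect_lt(focalLoss(p, y), 1e-7)
  expect_lt(abs(dscLoss(p, y)), 2e-6)
  expect_lt(abs(dscppLoss(p, y)), 2e-6)
  expect_lt(abs(tverskyLoss(p, y)), 4e-6)
  expect_lt(abs(focalTverskyLoss(p, y)), 2e-2)  # eps^{1/gamma} scale
  expect_lt(abs(unifiedFocalLoss(p, y)), 1e-4)
  expect_equal(comboLoss(p, y, comboAlpha = 0.5), -0.5, tolerance = 1e-5,
               ignore_attr = TRUE)
  # inverted binary prediction maxes the region losses
  expect_equal(as.numeric(dscppLoss(1 - p, y)), 1, tolerance = 1e-5)
  expect_equal(as.numeric(tverskyLoss(1 - p, y)), 2, tolerance = 1e-4)
})

test_that("identity ladder holds to 1e-12 on random inputs", {
  set.seed(99)
  for (rep in 1:50) {
    C <- sample(2:3, 1)
    p <- randomProbArray(c(5, 4, C))
    y <- oneHotEncode(randomMaskArray(c(5, 4), C), C)
    cfg <- LossConfig()
    # DSC++ at gamma 1 == independent overlap-form Dice implementation
    expect_equal(as.numeric(dscppLoss(p, y, gammaPP = 1)),
                 as.numeric(dscLoss(p, y)), tolerance = 1e-12)
    # focal at gamma 0, alpha 1 == CE
    expect_equal(as.numeric(focalLoss(p, y, alpha = 1, gamma = 0)),
                 as.numeric(ceLoss(p, y)), tolerance = 1e-12)
    # focal Tversky at ftGamma 1 == Tversky
    expect_equal(as.numeric(focalTverskyLoss(p, y, 0.3, 0.7, ftGamma = 1)),
                 as.numeric(tverskyLoss(p, y, 0.3, 0.7)), tolerance = 1e-12)
    # Tversky at alpha=beta=0.5 with doubled numerator, averaged == Dice
    expect_equal(as.numeric(tverskyLoss(p, y, 0.5, 0.5, average = TRUE,
                                        double = TRUE)),
                 as.numeric(dscppLoss(p, y, gammaPP = 1)), tolerance = 1e-12)
    # combo at alpha 1 == modified CE alone (Dice term weighted out)
    expect_equal(as.numeric(comboLoss(p, y, comboAlpha = 1, comboBeta = 0.3)),
                 as.numeric(comboLoss(p, y, comboAlpha = 1, comboBeta = 0.3,
                                      gammaPP = 2)), tolerance = 1e-12)
    # unified focal at lambda endpoints equals its single component
    ufAF <- unifiedFocalLoss(p, y, ufLambda = 1)
    ufAFT <- unifiedFocalLoss(p, y, ufLambda = 0)
    uf <- unifiedFocalLoss(p, y, ufLambda = 0.5)
    expect_equal(as.numeric(uf), 0.5 * as.numeric(ufAF) + 0.5 * as.numeric(ufAFT),
                 tolerance = 1e-12)
  }
})

test_that("combo mCE at beta = 0.5 halves the standard binary CE", {
  set.seed(4)
  for (rep in 1:10) {
    p <- randomProbArray(c(6, 6, 2))
    y <- oneHotEncode(randomMaskArray(c(6, 6), 2), 2)
    mce <- comboLoss(p, y, comboAlpha = 1, comboBeta = 0.5)
    expect_equal(as.numeric(mce), 0.5 * as.numeric(ceLoss(p, y)),
                 tolerance = 1e-10)
  }
})

test_that("vectorised losses match naive per-pixel loop oracles", {
  set.seed(13)
  shapes <- list(c(8, 8, 2), c(4, 8, 8, 3))
  for (dims in shapes) {
    spatial <- dims[-length(dims)]
    C <- dims[length(dims)]
    p <- randomProbArray(dims)
    y <- oneHotEncode(randomMaskArray(spatial, C), C)
    yv <- values(y)
    expect_equal(as.numeric(ceLoss(p, y)), oracleCE(p, yv), tolerance = 1e-10)
    expect_equal(as.numeric(focalLoss(p, y, alpha = 0.5, gamma = 2)),
                 oracleFocal(p, yv, 0.5, 2), tolerance = 1e-10)
    for (g in c(1, 2)) {
      expect_equal(as.numeric(dscppLoss(p, y, gammaPP = g)),
                   oracleDscpp(p, yv, g), tolerance = 1e-10)
      expect_equal(as.numeric(tverskyLoss(p, y, 0.3, 0.7, gammaPP = g)),
                   oracleTversky(p, yv, 0.3, 0.7, g), tolerance = 1e-10)
    }
    expect_equal(as.numeric(unifiedFocalLoss(p, y)),
                 oracleUnifiedFocal(p, yv, 0.5, 0.6, 0.5, 1),
                 tolerance = 1e-10)
    expect_equal(as.numeric(unifiedFocalLoss(p, y, gammaPP = 2)),
                 oracleUnifiedFocal(p, yv, 0.5, 0.6, 0.5, 2),
                 tolerance = 1e-10)
  }
})

test_that("the focal exponent selectively discounts unconfident errors", {
  # single erroneous pixel with confidence q: its error term is q^gamma,
  # strictly decreasing in gamma for q in (0, 1)
  q <- c(0.2, 0.5, 0.8, 0.99)
  gammas <- c(1, 1.5, 2, 3, 4)
  for (qi in q) {
    terms <- qi^gammas
    if (qi < 1) expect_true(all(diff(terms) < 0))
  }

  # loss ratio confident-vs-unconfident error grows with gamma
  mkP <- function(q) {
    pf <- c(1, 1, 0, q)      # one wrong pixel with confidence q
    array(c(1 - pf, pf), dim = c(1, 4, 2))
  }
  y <- oneHotEncode(LabelMask(matrix(c(1L, 1L, 0L, 0L), 1, 4)))
  cfg <- cfgForeground()
  ratio <- sapply(c(1, 2, 3, 4), function(g)
    as.numeric(dscppLoss(mkP(0.99), y, g, cfg)) /
    as.numeric(dscppLoss(mkP(0.5), y, g, cfg)))
  expect_true(all(diff(ratio) > 0))

  # holding correct pixels fixed, the loss is non-increasing in gamma
  losses <- sapply(c(1, 1.5, 2, 3), function(g)
    as.numeric(dscppLoss(mkP(0.7), y, g, cfg)))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("loss parameter validation errors fire", {
  ex <- fourPixelExample()
  expect_error(focalLoss(ex$p, ex$y, alpha = c(1, 1, 1)), "length")
  expect_error(tverskyLoss(ex$p, ex$y, alpha = 0, beta = 0), "degenerate")
  expect_error(focalTverskyLoss(ex$p, ex$y, ftGamma = 0), "ftGamma")
  expect_error(unifiedFocalLoss(ex$p, ex$y, rareClass = 5), "rareClass")
  expect_error(dscppLoss(ex$p, ex$y, gammaPP = -1), "positive")
  expect_warning(dscppLoss(ex$p, ex$y, gammaPP = 0.5), "grid")
  expect_error(lossValue("nope", ex$p, ex$y), "unknown loss")
  expect_error(ceLoss(array(0.5, c(2, 2, 2)), oneHotEncode(matrix(0L, 3, 3), 2)),
               "shape mismatch")
})

test_that("LossConfig defaults match the standard hyperparameter settings", {
  cfg <- LossConfig()
  expect_equal(cfg@focalAlpha, 0.5)
  expect_equal(cfg@focalGamma, 2)
  expect_equal(cfg@tverskyAlpha, 0.3)
  expect_equal(cfg@tverskyBeta, 0.7)
  expect_equal(cfg@ftGamma, 4 / 3)
  expect_equal(cfg@comboAlpha, 0.5)
  expect_equal(cfg@comboBeta, 0.5)
  expect_equal(cfg@ufGamma, 0.5)
  expect_equal(cfg@ufDelta, 0.6)
  expect_equal(cfg@ufLambda, 0.5)
  expect_equal(cfg@gammaPP, 2)
  expect_error(LossConfig(ufGamma = 1.2), "ufGamma")
  expect_error(LossConfig(bogus = 1), "unknown")
})
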