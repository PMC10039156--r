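# Calibration and overlap metrics, bootstrap SEs, dataset evaluation.

test_that("nll shares the CE implementation and brier matches hand values", {
  set.seed(3)
  p <- randomProbArray(c(6, 6, 3))
  y <- oneHotEncode(randomMaskArray(c(6, 6), 3), 3)
  expect_identical(nll(p, y), as.numeric(ceLoss(p, y)))

  y2 <- oneHotEncode(LabelMask(matrix(c(0L, 1L), 1, 2)))
  p2 <- array(c(0.9, 0.4, 0.1, 0.6), dim = c(1, 2, 2))
  expect_equal(brier(p2, y2), 0.085, tolerance = 1e-12)
  expect_equal(brier(values(y2), y2), 0)
  pu <- array(0.5, dim = c(1, 2, 2))
  expect_equal(brier(pu, y2), 0.25, tolerance = 1e-12)
})

test_that("hard overlap metrics match direct arithmetic", {
  # TP=3, FP=1, FN=2 on the foreground class
  truth <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2, 5)
  pred <- truth
  pred[truth == 1][1:2] <- 0   # two FN
  pred[truth == 0][1] <- 1     # one FP
  m <- hardOverlapMetrics(pred, truth, 2)
  fg <- m$perClass["class1", ]
  expect_equal(unname(fg["dice"]), 6 / 9, tolerance = 1e-12)
  expect_equal(unname(fg["jaccard"]), 0.5)
  expect_equal(unname(fg["recall"]), 0.6)
  expect_equal(unname(fg["precision"]), 0.75)

  expect_true(all(hardOverlapMetrics(truth, truth, 2)$perClass == 1))
  disjoint <- 1 - truth
  expect_true(all(hardOverlapMetrics(disjoint, truth, 2)$perClass == 0))
})

test_that("jaccard equals dice/(2 - dice) over random confusion counts", {
  set.seed(8)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp + fn == 0) next
    dice <- 2 * tp / (2 * tp + fp + fn)
    jac <- tp / (tp + fp + fn)
    expect_equal(jac, dice / (2 - dice), tolerance = 1e-12)
  }
  # and on real masks via the evaluator
  set.seed(9)
  truth <- randomMaskArray(c(10, 10), 2)
  pred <- randomMaskArray(c(10, 10), 2)
  m <- hardOverlapMetrics(pred, truth, 2)$perClass
  expect_equal(m[, "jaccard"], m[, "dice"] / (2 - m[, "dice"]),
               tolerance = 1e-12)
  expect_true(all(m[, "jaccard"] <= m[, "dice"] + 1e-12))
})

test_that("bootstrap SE is deterministic and matches the closed form", {
  x <- rep(c(0, 1), 50)
  se <- bootstrapSE(x, nBoot = 10000, seed = 42)
  analytic <- stats::sd(x) / sqrt(length(x))   # about 0.05
  expect_lt(abs(se - analytic) / analytic, 0.05)
  expect_identical(bootstrapSE(x, 500, seed = 7), bootstrapSE(x, 500, seed = 7))
  expect_equal(bootstrapSE(rep(3.2, 10), 200, seed = 1), 0)
  expect_error(bootstrapSE(1, 1000, seed = 1), "insufficient")
  expect_error(bootstrapSE(c(1, 2), 10, seed = 1), "nBoot")
})

test_that("evaluateDataset composes the single-image metrics", {
  set.seed(12)
  ds <- generateDataset(3, c(24, 24), "blob", fgFraction = 0.1, seed = 2)
  truths <- lapply(ds, `[[`, "mask")
  preds <- lapply(seq_along(truths), function(i)
    simulatePredictor(truths[[i]], tau = 1.5, k = 2, flipFraction = 0.02,
                      seed = 20 + i))
  rep <- evaluateDataset(preds, truths, nBoot = 200, seed = 5)
  pi <- perImage(rep)
  expect_equal(nrow(pi), 3)
  # rows match the single-image operations exactly
  for (i in 1:3) {
    y <- oneHotEncode(truths[[i]])
    expect_equal(pi$nll[i], nll(preds[[i]], y))
    expect_equal(pi$brier[i], brier(preds[[i]], y))
    ov <- hardOverlapMetrics(decodeLabels(preds[[i]]), truths[[i]])
    expect_equal(pi$dice[i], unname(ov$mean["dice"]))
  }
  # aggregates are arithmetic means
  expect_equal(unname(aggregateMetrics(rep)["nll"]), mean(pi$nll))
  expect_equal(unname(aggregateMetrics(rep)["dice"]), mean(pi$dice))

  # a perfect prediction scores perfectly
  y1 <- oneHotEncode(truths[[1]])
  rep1 <- evaluateDataset(list(values(y1)), truths[1], nBoot = 200, seed = 1)
  a <- aggregateMetrics(rep1)
  expect_lt(a["nll"], 1e-6)
  expect_equal(unname(a["brier"]), 0)
  expect_equal(unname(a["dice"]), 1)
  expect_equal(unname(a["jaccard"]), 1)

  expect_error(evaluateDataset(preds, truths[1:2]), "length mismatch")
})

test_that("sharpening worsens calibration but not hard overlap", {
  ds <- generateDataset(3, c(48, 48), "blob", fgFraction = 0.06, seed = 31)
  for (i in seq_along(ds)) {
    truth <- ds[[i]]$mask
    y <- oneHotEncode(truth)
    soft <- simulatePredictor(truth, tau = 2, k = 1, flipFraction = 0.02,
                              seed = 40 + i)
    sharp <- simulatePredictor(truth, tau = 2, k = 10, flipFraction = 0.02,
                               seed = 40 + i)
    expect_gt(nll(sharp, y), nll(soft, y))
    expect_gt(brier(sharp, y), brier(soft, y))
    expect_identical(values(decodeLabels(soft)), values(decodeLabels(sharp)))
  }
})

test_that("nll and brier are proper-score sane: truth-matching p scores best", {
  set.seed(77)
  m <- randomMaskArray(c(8, 8), 2)
  y <- oneHotEncode(m, 2)
  best <- values(y)
  for (rep in 1:10) {
    other <- randomProbArray(c(8, 8, 2))
    expect_lte(nll(best, y), nll(other, y))
    expect_lte(brier(best, y), brier(other, y))
  }
})

test_that("metric report round-trips through CSV", {
  ds <- generateDataset(2, c(16, 16), "blob", fgFraction = 0.1, seed = 8)
  truths <- lapply(ds, `[[`, "mask")
  preds <- lapply(truths, function(t)
    simulatePredictor(t, tau = 1, k = 1, flipFraction = 0, seed = 2))
  rep <- evaluateDataset(preds, truths, nBoot = 200, seed = 3)
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  writeMetricReport(rep, csv = csv, json = json)
  back <- utils::read.csv(csv)
  expect_equal(names(back),
               c("id", "nll", "brier", "dice", "jaccard", "recall", "precision"))
  expect_equal(back$dice, perImage(rep)$dice, tolerance = 1e-12)
  agg <- jsonlite::read_json(json)
  expect_equal(agg$aggregate$nll, unname(aggregateMetrics(rep)["nll"]),
               tolerance = 1e-9)
})
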