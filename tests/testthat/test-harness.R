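# Experiment harness: splits, callbacks, adapter/reference loss agreement,
# and a training smoke test.

test_that("dataset splits are 64/16/20, disjoint, exhaustive, deterministic", {
  sp <- splitDataset(1:100, seed = 1)
  expect_equal(lengths(sp), c(train = 64L, val = 16L, test = 20L))
  all3 <- c(sp$train, sp$val, sp$test)
  expect_setequal(all3, 1:100)
  expect_equal(length(unique(all3)), 100)
  expect_identical(splitDataset(1:100, seed = 1), sp)
  expect_false(identical(splitDataset(1:100, seed = 2), sp))
  expect_error(splitDataset(1:4, seed = 1), "too few")
})

test_that("callbacks reduce the LR after patience and stop after stopPatience", {
  # scripted, monotonically worsening validation loss
  cb <- makeCallbacks(lrInit = 0.1, factor = 0.1, lrPatience = 3,
                      stopPatience = 7)
  losses <- seq(1, by = 0.1, length.out = 12)
  lrs <- stops <- c()
  for (l in losses) {
    act <- cb$update(l)
    lrs <- c(lrs, act$lr)
    stops <- c(stops, act$stop)
    if (act$stop) break
  }
  # epoch 1 improves (best = 1); epochs 2-4 wait 1..3 -> LR drops at epoch 4
  expect_equal(lrs[1:3], rep(0.1, 3))
  expect_equal(lrs[4], 0.01, tolerance = 1e-12)
  # next plateau of 3 -> second drop at epoch 7
  expect_equal(lrs[7], 0.001, tolerance = 1e-12)
  # early stop at 7 non-improving epochs -> epoch 8
  expect_true(stops[length(stops)])
  expect_equal(length(lrs), 8)

  # an improvement resets both counters
  cb2 <- makeCallbacks(0.1, 0.1, 2, 4)
  for (l in c(1, 1.1, 0.9, 1.0, 1.0)) act <- cb2$update(l)
  expect_equal(act$lr, 0.01, tolerance = 1e-12)  # one drop after the reset
  expect_false(act$stop)
})

test_that("the adapter's plumbed loss equals the reference loss", {
  set.seed(31)
  ad <- tinyUNetAdapter(c(16, 16), 2, 4, seed = 3)
  img <- matrix(rnorm(256), 16, 16)
  y <- oneHotEncode(matrix(sample(0:1, 256, TRUE), 16, 16), 2)
  for (nm in c("dsc++", "ce", "tversky++")) {
    viaAdapter <- ad$lossOn(img, y, nm, LossConfig())
    direct <- lossValue(nm, ad$predict(img), y, LossConfig())
    expect_equal(viaAdapter, direct, tolerance = 1e-6)
  }
})

test_that("one SGD step through the adapter reduces the loss", {
  set.seed(32)
  ad <- tinyUNetAdapter(c(16, 16), 2, 4, seed = 5)
  img <- matrix(rnorm(256), 16, 16)
  m <- matrix(0L, 16, 16); m[5:9, 5:9] <- 1L
  y <- oneHotEncode(m, 2)
  before <- ad$lossOn(img, y, "dsc++", LossConfig())
  for (i in 1:5) ad$step(img, y, "dsc++", LossConfig(), lr = 0.05)
  after <- ad$lossOn(img, y, "dsc++", LossConfig())
  expect_lt(after, before)
})

test_that("a short experiment runs end to end and is seed-reproducible", {
  cfg <- experimentConfig(lossName = "dsc++",
                          lossConfig = LossConfig(gammaPP = 2,
                                                  includeBackground = FALSE),
                          nImages = 20, shape = c(32, 32), maxEpochs = 3,
                          seed = 0, nBoot = 100)
  res <- runExperiment(cfg)
  expect_s4_class(res$report, "MetricReport")
  expect_equal(nrow(res$curves), 3)
  # training reduces the loss over the smoke run
  expect_lt(res$curves$trainLoss[3], res$curves$trainLoss[1])
  # identical config and seeds reproduce the final metrics exactly
  res2 <- runExperiment(cfg)
  expect_identical(aggregateMetrics(res$report), aggregateMetrics(res2$report))
  expect_identical(res$testIdx, res2$testIdx)
})

test_that("the gamma grid shares splits and sorts its table", {
  cfg <- experimentConfig(nImages = 15, shape = c(16, 16), maxEpochs = 1,
                          fgFraction = 0.1, seed = 1, nBoot = 100)
  gs <- suppressWarnings(gammaGridSearch(cfg, gammas = c(2, 0.5)))
  expect_equal(gs$table$gamma, c(0.5, 2))
  expect_identical(gs$runs[[1]]$testIdx, gs$runs[[2]]$testIdx)
  # a single-gamma grid equals a direct run
  gs1 <- gammaGridSearch(cfg, gammas = 2)
  cfg2 <- cfg; cfg2$lossName <- "dsc++"; cfg2$lossConfig@gammaPP <- 2
  direct <- runExperiment(cfg2)
  expect_equal(gs1$table$nll, unname(aggregateMetrics(direct$report)["nll"]))
  expect_error(gammaGridSearch(cfg, numeric(0)), "non-empty")
})

test_that("the default gamma grid spans 0.5 to 5 in steps of 0.5", {
  expect_equal(eval(formals(gammaGridSearch)$gammas), seq(0.5, 5, by = 0.5))
})
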