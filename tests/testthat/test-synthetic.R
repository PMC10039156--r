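# Synthetic data generation, simulated predictors, augmentation, patches.

test_that("generation is deterministic and seeds differentiate", {
  a <- generateDataset(3, c(32, 32), "blob", fgFraction = 0.05, seed = 0)
  b <- generateDataset(3, c(32, 32), "blob", fgFraction = 0.05, seed = 0)
  c <- generateDataset(3, c(32, 32), "blob", fgFraction = 0.05, seed = 1)
  expect_identical(lapply(a, function(x) values(x$mask)),
                   lapply(b, function(x) values(x$mask)))
  expect_identical(a[[1]]$image, b[[1]]$image)
  expect_false(identical(values(a[[1]]$mask), values(c[[1]]$mask)))
})

test_that("realised foreground fractions track the target", {
  ds <- generateDataset(100, c(64, 64), "blob", fgFraction = 0.05, seed = 2)
  fr <- vapply(ds, function(x) mean(values(x$mask) != 0), numeric(1))
  expect_gt(mean(fr), 0.025)
  expect_lt(mean(fr), 0.075)
  dsv <- generateDataset(20, c(64, 64), "vessel", fgFraction = 0.05, seed = 2)
  frv <- vapply(dsv, function(x) mean(values(x$mask) != 0), numeric(1))
  expect_gt(mean(frv), 0.025)
  expect_lt(mean(frv), 0.075)
})

test_that("vessel foreground is 8-connected and thin", {
  ds <- generateDataset(5, c(48, 48), "vessel", fgFraction = 0.04, seed = 7)
  for (x in ds) {
    m <- values(x$mask)
    expect_true(isConnected8(m))
    expect_gt(mean(m != 0), 0.005)
  }
})

test_that("the organ kind nests a lesion inside the organ", {
  ds <- generateDataset(4, c(48, 48), "organ", fgFraction = 0.15, seed = 3)
  for (x in ds) {
    m <- values(x$mask)
    expect_setequal(sort(unique(as.vector(m))), 0:2)
    expect_equal(nClasses(x$mask), 3L)
    # lesion pixels are scarcer than organ pixels
    expect_lt(sum(m == 2), sum(m == 1) + sum(m == 2))
  }
})

test_that("infeasible fraction/shape combinations are rejected", {
  expect_error(generateDataset(1, c(64, 64), "blob", fgFraction = 0.7,
                               seed = 1), "fgFraction")
  # a blob of the target area cannot fit across the short axis
  expect_error(generateDataset(1, c(4, 40), "blob", fgFraction = 0.45,
                               seed = 1), "infeasible")
})

test_that("the squared EDT matches the EBImage oracle", {
  skip_if_not_installed("EBImage")
  set.seed(18)
  for (rep in 1:3) {
    m <- matrix(runif(30 * 20) < 0.08, 30, 20)
    m[sample(600, 1)] <- TRUE     # at least one feature pixel
    d1 <- sqrt(edtSquared(m))
    d2 <- EBImage::distmap(1 - m)  # background-pixel distance to nearest TRUE
    expect_equal(d1, matrix(as.numeric(d2), 30, 20), tolerance = 1e-12)
  }
})

test_that("simulated predictors honour their contract", {
  ds <- generateDataset(2, c(40, 40), "blob", fgFraction = 0.08, seed = 4)
  m <- ds[[1]]$mask
  # k = 1, no flips: argmax recovers the truth everywhere
  p <- simulatePredictor(m, tau = 2, k = 1, flipFraction = 0, seed = 1)
  expect_s4_class(p, "ProbabilityMap")
  expect_identical(values(decodeLabels(p)), values(m))
  # determinism
  p2 <- simulatePredictor(m, tau = 2, k = 1, flipFraction = 0.05, seed = 9)
  p3 <- simulatePredictor(m, tau = 2, k = 1, flipFraction = 0.05, seed = 9)
  expect_identical(values(p2), values(p3))
  # sharpening preserves the argmax pixelwise, also in flipped regions
  p4 <- simulatePredictor(m, tau = 2, k = 6, flipFraction = 0.05, seed = 9)
  expect_identical(values(decodeLabels(p2)), values(decodeLabels(p4)))
  # multi-class truth works too
  dso <- generateDataset(1, c(40, 40), "organ", fgFraction = 0.15, seed = 5)
  po <- simulatePredictor(dso[[1]]$mask, tau = 2, k = 1, flipFraction = 0,
                          seed = 2)
  expect_identical(values(decodeLabels(po)), values(dso[[1]]$mask))
  expect_error(simulatePredictor(m, tau = 0, seed = 1), "tau")
  expect_error(simulatePredictor(m, k = 0.5, seed = 1), "k must")
  expect_error(simulatePredictor(m, flipFraction = 0.6, seed = 1), "flip")
})

test_that("augmentation transforms behave as documented", {
  set.seed(22)
  img <- matrix(rnorm(32 * 32), 32, 32)
  mask <- matrix(sample(0:1, 32 * 32, TRUE, prob = c(0.9, 0.1)), 32, 32)

  # no-augment branch is the identity
  id <- applyAugmentation(img, mask, "identity")
  expect_identical(id$image, img)
  expect_identical(id$mask, mask)
  set.seed(1)                  # runif(1) = 0.27 >= prob 0.15: no augmentation
  out <- augment(img, mask, prob = 0.15)
  expect_identical(out$transform, "identity")
  expect_identical(out$image, img)

  # mirroring twice along the same axis is the identity
  for (ax in 1:2) {
    m1 <- applyAugmentation(img, mask, "mirror", list(axis = ax))
    m2 <- applyAugmentation(m1$image, m1$mask, "mirror", list(axis = ax))
    expect_equal(m2$image, img)
    expect_identical(m2$mask, mask)
  }

  # rotation keeps labels in the original label set
  rot <- applyAugmentation(img, mask, "rotate", list(angle = 15))
  expect_true(all(rot$mask %in% c(0L, 1L)))
  expect_identical(dim(rot$mask), dim(mask))

  # elastic deformation keeps labels integral
  ela <- applyAugmentation(img, mask, "elastic",
                           list(alpha = 300, sigma = 10))
  expect_true(all(ela$mask %in% c(0L, 1L)))

  # brightness scales the image only
  br <- applyAugmentation(img, mask, "brightness", list(factor = 2))
  expect_equal(br$image, 2 * img)
  expect_identical(br$mask, mask)

  # 3-D: mirroring works, geometric warps refuse
  vol <- array(rnorm(4^3), c(4, 4, 4))
  vmask <- array(0L, c(4, 4, 4))
  m3 <- applyAugmentation(vol, vmask, "mirror", list(axis = 3))
  expect_equal(applyAugmentation(m3$image, m3$mask, "mirror",
                                 list(axis = 3))$image, vol)
  expect_error(applyAugmentation(vol, vmask, "rotate", list(angle = 5)),
               "2-D")
})

test_that("patch sampling covers the stride grid", {
  vol <- array(seq_len(16^3), c(16, 16, 16))
  mask <- array(0L, c(16, 16, 16))
  # patch == volume: single patch equal to the volume
  ps <- samplePatches(vol, mask, c(16, 16, 16), overlap = c(0, 0, 0), seed = 1)
  expect_length(ps, 1)
  expect_equal(ps[[1]]$patch, vol)

  # 8^3 patches with 4^3 overlap: stride-4 grid, 27 origins
  ps <- samplePatches(vol, mask, c(8, 8, 8), overlap = c(4, 4, 4), seed = 1)
  expect_length(ps, 27)
  origins <- t(vapply(ps, `[[`, integer(3), "origin"))
  expect_setequal(unique(origins[, 1]), c(1L, 5L, 9L))
  expect_true(all(vapply(ps, function(x)
    identical(dim(x$patch), c(8L, 8L, 8L)), logical(1))))
  # grid covers the volume: last origin + patch - 1 reaches the edge
  expect_equal(max(origins[, 1]) + 8L - 1L, 16L)

  # determinism of the origin sequence
  ps2 <- samplePatches(vol, mask, c(8, 8, 8), overlap = c(4, 4, 4), seed = 1)
  expect_identical(lapply(ps, `[[`, "origin"), lapply(ps2, `[[`, "origin"))

  expect_error(samplePatches(vol, mask, c(32, 8, 8)), "fit inside")
  expect_error(samplePatches(vol, mask, c(8, 8, 8), overlap = c(8, 4, 4)),
               "overlap")
})

test_that("z-score normalisation centres, scales and ignores affine maps", {
  set.seed(25)
  img <- array(rnorm(100, mean = 5, sd = 3), c(10, 10))
  z <- zscoreNormalize(img)
  expect_lt(abs(mean(z)), 1e-8)
  expect_lt(abs(stats::sd(z) - 1), 1e-8)
  expect_equal(zscoreNormalize(3 * img + 7), z, tolerance = 1e-10)
  expect_warning(zc <- zscoreNormalize(array(2, c(4, 4))), "constant")
  expect_true(all(zc == 0))
})
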