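## Synthetic class-imbalanced segmentation data and simulated predictor
## outputs, so losses, metrics, thresholding and training can be exercised
## without any external dataset. Blob targets emulate lesion/nucleus-like
## structures, vessel targets thin curvilinear retinal-vessel-like
## structures, and the organ kind a nested multi-class target (organ with an
## internal lesion).

## ---- squared Euclidean distance transform --------------------------------

## Separable lower-envelope 1-D distance transform (squared distances).
## `f` is the column of squared distances so far; returns the transformed
## column. Uses a large finite stand-in for +Inf to keep the parabola
## intersections well defined.
.dtBig <- 1e12

.dt1d <- function(f) {
  n <- length(f)
  if (n == 1) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -.dtBig; z[2] <- .dtBig
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- .dtBig
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

.dtAxis <- function(f, ax) {
  d <- dim(f)
  perm <- c(ax, seq_along(d)[-ax])
  m <- matrix(aperm(f, perm), nrow = d[ax])
  m <- apply(m, 2, .dt1d)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Squared Euclidean distance transform
#'
#' For each cell of a logical array, the squared Euclidean distance to the
#' nearest `TRUE` cell, computed by the separable lower-envelope algorithm
#' (exact, O(n) per axis). Works for 2-D and 3-D grids. An array with no
#' `TRUE` cell returns a large finite sentinel everywhere.
#'
#' @param feature logical (or 0/1) array; distances are measured to the
#'   `TRUE` cells.
#' @return Numeric array of squared distances, same shape.
#' @export
edtSquared <- function(feature) {
  d <- dim(feature)
  if (is.null(d)) stop("feature must be an array")
  f <- array(ifelse(feature != 0, 0, .dtBig), dim = d)
  for (ax in seq_along(d)) f <- .dtAxis(f, ax)
  f
}

## Signed distance to the boundary of region (mask == classId): positive
## inside, negative outside, never zero (pixel centres are >= 1 away from
## the nearest opposite pixel).
.signedDistance <- function(mask, classId) {
  inside <- mask == classId
  dIn <- sqrt(edtSquared(!inside))   # fg pixel -> nearest bg pixel
  dOut <- sqrt(edtSquared(inside))   # bg pixel -> nearest fg pixel
  ifelse(inside, dIn, -dOut)
}

## ---- shape stamping helpers ----------------------------------------------

.gridCoords <- function(shape) {
  lapply(seq_along(shape), function(ax) {
    reps <- shape
    coord <- seq_len(shape[ax])
    array(rep(coord, each = prod(shape[seq_len(ax - 1)])), dim = shape)
  })
}

.stampEllipse <- function(mask, center, radii, label) {
  co <- .gridCoords(dim(mask))
  acc <- 0
  for (ax in seq_along(co))
    acc <- acc + ((co[[ax]] - center[ax]) / radii[ax])^2
  mask[acc <= 1] <- label
  mask
}

.stampDisc <- function(mask, center, radius, label) {
  .stampEllipse(mask, center, rep(radius, length(dim(mask))), label)
}

## ---- dataset generation ---------------------------------------------------

.genBlobMask <- function(shape, fgFraction) {
  r <- length(shape)
  mask <- array(0L, dim = shape)
  targetVol <- fgFraction * prod(shape)
  nBlob <- sample(1:3, 1)
  share <- stats::runif(nBlob, 0.5, 1.5)
  share <- share / sum(share) * targetVol
  for (b in seq_len(nBlob)) {
    baseR <- if (r == 2) sqrt(share[b] / pi) else (share[b] * 3 / (4 * pi))^(1 / 3)
    ecc <- stats::runif(r, 0.7, 1.3)
    ecc <- ecc / prod(ecc)^(1 / r)        # keep the volume fixed
    radii <- pmax(baseR * ecc, 1)
    lo <- radii + 1
    hi <- shape - radii
    if (any(hi < lo)) { lo <- pmin(lo, shape / 2); hi <- pmax(hi, shape / 2) }
    center <- mapply(function(a, b) stats::runif(1, a, b), lo, hi)
    mask <- .stampEllipse(mask, center, radii, 1L)
  }
  mask
}

.genVesselMask <- function(shape, fgFraction) {
  r <- length(shape)
  mask <- array(0L, dim = shape)
  targetVol <- fgFraction * prod(shape)
  centreline <- NULL                      # points already on the vessel tree
  stamp <- function(mask, pos, halfw) {
    if (halfw <= 0.5) {
      idx <- matrix(round(pos), 1)
      if (all(idx >= 1 & idx <= shape)) mask[idx] <- 1L
      mask
    } else .stampDisc(mask, pos, halfw, 1L)
  }
  tries <- 0
  while (sum(mask) < targetVol && tries < 40) {
    tries <- tries + 1
    halfw <- stats::runif(1, 0.5, 1.5)    # vessel widths ~ 1-3 px
    ## branches start on the existing tree so the foreground stays connected
    pos <- if (is.null(centreline)) stats::runif(r, shape * 0.2, shape * 0.8)
           else centreline[sample.int(nrow(centreline), 1), ] + 0
    dir <- stats::rnorm(r)
    dir <- dir / sqrt(sum(dir^2))
    len <- round(stats::runif(1, 0.4, 1.0) * max(shape))
    for (step in seq_len(len)) {
      mask <- stamp(mask, pos, halfw)
      centreline <- rbind(centreline, pos)
      turn <- stats::rnorm(r, sd = 0.25)
      dir <- dir + turn
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      if (any(pos < 1.5) || any(pos > shape - 0.5)) break
    }
    if (sum(mask) >= targetVol) break
  }
  mask
}

.genOrganMask <- function(shape, fgFraction) {
  r <- length(shape)
  mask <- array(0L, dim = shape)
  targetVol <- fgFraction * prod(shape)
  baseR <- if (r == 2) sqrt(targetVol / pi) else (targetVol * 3 / (4 * pi))^(1 / 3)
  ecc <- stats::runif(r, 0.8, 1.2)
  ecc <- ecc / prod(ecc)^(1 / r)
  radii <- pmax(baseR * ecc, 2)
  lo <- radii + 1; hi <- shape - radii
  if (any(hi < lo)) { lo <- pmin(lo, shape / 2); hi <- pmax(hi, shape / 2) }
  center <- mapply(function(a, b) stats::runif(1, a, b), lo, hi)
  mask <- .stampEllipse(mask, center, radii, 1L)
  ## lesion: a smaller blob inside the organ
  lesionR <- pmax(radii * stats::runif(1, 0.25, 0.45), 1)
  off <- stats::runif(r, -0.3, 0.3) * radii
  mask <- .stampEllipse(mask, center + off, lesionR, 2L)
  mask
}

#' Generate a synthetic class-imbalanced segmentation dataset
#'
#' Produces `nImages` pairs of intensity image and ground-truth label mask
#' on a 2-D or 3-D grid. Three structure kinds are available: `"blob"`
#' (elliptical lesion/nucleus-like targets), `"vessel"` (connected thin
#' curvilinear structures, width about 1-3 px, grown as random walks with
#' branches rooted on the existing tree) and `"organ"` (three classes: a
#' large organ containing a smaller, brighter lesion). Images carry class
#' intensity contrast (background 0.3, foreground 0.7, lesion 0.9) plus
#' additive Gaussian noise. Generation is deterministic given `seed` and
#' leaves the caller's RNG state untouched.
#'
#' @param nImages number of images.
#' @param shape spatial grid, e.g. `c(64, 64)` or `c(16, 32, 32)`.
#' @param kind one of `"blob"`, `"vessel"`, `"organ"`.
#' @param fgFraction target foreground fraction in `(0, 0.5)`; realised
#'   fractions vary around it (within about +/-50%).
#' @param noise standard deviation of the additive Gaussian noise.
#' @param seed mandatory integer seed.
#' @return A list of `nImages` elements, each `list(image = array,
#'   mask = LabelMask)`.
#' @examples
#' ds <- generateDataset(2, c(32, 32), "blob", fgFraction = 0.1, seed = 1)
#' ds[[1]]$mask
#' @export
generateDataset <- function(nImages, shape = c(64, 64),
                            kind = c("blob", "vessel", "organ"),
                            fgFraction = 0.05, noise = 0.1, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is mandatory")
  if (fgFraction <= 0 || fgFraction >= 0.5)
    stop("fgFraction must lie in (0, 0.5)")
  if (!length(shape) %in% c(2, 3)) stop("shape must have rank 2 or 3")
  minR <- if (length(shape) == 2) sqrt(fgFraction * prod(shape) / pi)
          else (fgFraction * prod(shape) * 3 / (4 * pi))^(1 / 3)
  if (kind != "vessel" && minR * 2 > min(shape))
    stop("infeasible fraction/shape combination: target structure does not fit")
  levels <- c(0.3, 0.7, 0.9)
  .withSeed(seed, {
    lapply(seq_len(nImages), function(i) {
      mask <- switch(kind,
        blob = .genBlobMask(shape, fgFraction),
        vessel = .genVesselMask(shape, fgFraction),
        organ = .genOrganMask(shape, fgFraction))
      img <- levels[mask + 1L] + stats::rnorm(length(mask), sd = noise)
      list(image = array(img, dim = shape),
           mask = LabelMask(mask, nClasses = if (kind == "organ") 3L else 2L))
    })
  })
}

## ---- simulated predictor --------------------------------------------------

#' Simulate a (mis)calibrated predictor for a known truth
#'
#' Builds a probability map whose per-class score is the signed Euclidean
#' distance to the class boundary passed through a softmax with length
#' scale `tau`, so probabilities are graded near boundaries and confident
#' in structure interiors — the behaviour of a well-calibrated segmenter.
#' Two controlled corruptions emulate miscalibration: `flipFraction`
#' introduces clustered label errors (the true-class and strongest
#' competitor probabilities are swapped, so the argmax is wrong there), and
#' the sharpening exponent `k` raises all probabilities to the `k`-th power
#' and renormalises, pushing mass towards 0/1 without changing any argmax
#' — an overconfident predictor with the same segmentation.
#'
#' @param truth a [LabelMask-class] or integer array.
#' @param tau boundary length scale in pixels (`> 0`); default 2.
#' @param k sharpening exponent (`>= 1`); `k = 1` leaves the map
#'   calibrated.
#' @param flipFraction fraction of pixels in `[0, 0.5)` receiving flipped
#'   predictions (placed as small clusters).
#' @param seed mandatory integer seed (governs flip placement).
#' @return A [ProbabilityMap-class].
#' @examples
#' m <- generateDataset(1, c(32, 32), "blob", fgFraction = 0.1,
#'                      seed = 1)[[1]]$mask
#' p <- simulatePredictor(m, tau = 2, k = 1, flipFraction = 0, seed = 1)
#' all(values(decodeLabels(p)) == values(m))
#' @export
simulatePredictor <- function(truth, tau = 2, k = 1, flipFraction = 0, seed) {
  if (tau <= 0) stop("tau must be > 0")
  if (k < 1) stop("k must be >= 1")
  if (flipFraction < 0 || flipFraction >= 0.5)
    stop("flipFraction must lie in [0, 0.5)")
  if (missing(seed)) stop("seed is mandatory")
  mask <- .maskValues(truth)
  C <- if (is(truth, "LabelMask")) nClasses(truth) else max(2, max(mask) + 1)
  shape <- dim(mask)
  N <- prod(shape)
  Z <- vapply(seq_len(C) - 1L,
              function(c) as.vector(.signedDistance(mask, c)) / tau,
              numeric(N))
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  .withSeed(seed, {
    if (flipFraction > 0) {
      nFlip <- round(flipFraction * N)
      flip <- logical(N)
      rad <- if (length(shape) == 2) 2 else 1.5
      guard <- 0
      while (sum(flip) < nFlip && guard < 10 * N) {
        guard <- guard + 1
        center <- vapply(shape, function(s) stats::runif(1, 1, s), numeric(1))
        blob <- array(FALSE, dim = shape)
        blob <- .stampDisc(blob, center, rad, TRUE)
        flip <- flip | as.vector(blob)
      }
      flipIdx <- which(flip)[seq_len(min(nFlip, sum(flip)))]
      ## flipped pixels become low-confidence errors: the wrong class wins
      ## with modest probability, so sharpening turns them into confident
      ## errors (the overconfidence failure mode)
      u <- stats::runif(length(flipIdx), 0.55, 0.75)
      for (j in seq_along(flipIdx)) {
        i <- flipIdx[j]
        trueCol <- mask[i] + 1L
        other <- order(P[i, ], decreasing = TRUE)
        other <- other[other != trueCol][1]
        P[i, ] <- 0
        P[i, trueCol] <- 1 - u[j]
        P[i, other] <- u[j]
      }
    }
  })
  if (k > 1) {
    P <- P^k
    P <- P / rowSums(P)
  }
  ProbabilityMap(array(P, dim = c(shape, C)))
}

## ---- patch sampling and normalisation -------------------------------------

#' Sample training patches from a volume on a stride grid
#'
#' Patch origins lie on the stride grid implied by the requested overlap
#' (`stride = patchShape - overlap`), with an extra final origin per axis
#' so the grid always covers the full volume. Origins are returned in
#' random order (deterministic given `seed`), optionally truncated to `n`.
#'
#' @param volume numeric array (rank 2 or 3).
#' @param mask matching [LabelMask-class] or integer array.
#' @param patchShape integer vector, `<= dim(volume)` elementwise.
#' @param overlap integer vector, `< patchShape` elementwise.
#' @param n number of patches to return; default all grid positions.
#' @param seed integer seed for the origin shuffle.
#' @return List of `list(patch, maskPatch, origin)`.
#' @export
samplePatches <- function(volume, mask, patchShape, overlap = patchShape %/% 2,
                          n = NULL, seed = 1) {
  vol <- volume
  mv <- .maskValues(mask)
  d <- dim(vol)
  .checkSameShape(vol, mv, "volume and mask")
  if (length(patchShape) != length(d) || any(patchShape > d))
    stop("shape error: patch must fit inside the volume")
  if (any(overlap >= patchShape) || any(overlap < 0))
    stop("overlap must be non-negative and < patchShape elementwise")
  stride <- patchShape - overlap
  axes <- lapply(seq_along(d), function(ax) {
    o <- seq(1L, d[ax] - patchShape[ax] + 1L, by = stride[ax])
    last <- d[ax] - patchShape[ax] + 1L
    if (o[length(o)] != last) o <- c(o, last)
    o
  })
  grid <- as.matrix(expand.grid(axes))
  ord <- .withSeed(seed, sample.int(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  if (!is.null(n)) grid <- grid[seq_len(min(n, nrow(grid))), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    o <- grid[i, ]
    idx <- lapply(seq_along(d), function(ax) o[ax]:(o[ax] + patchShape[ax] - 1L))
    patch <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
    mpatch <- do.call(`[`, c(list(mv), idx, list(drop = FALSE)))
    list(patch = array(patch, dim = patchShape),
         maskPatch = array(mpatch, dim = patchShape),
         origin = as.integer(o))
  })
}

#' Z-score normalise an image
#'
#' Centres and scales an image to mean 0, standard deviation 1 (the
#' per-image normalisation used before feeding images to a model). A
#' constant image is returned as all zeros with a warning.
#'
#' @param image numeric array with at least 2 cells.
#' @return Array of the same shape.
#' @export
zscoreNormalize <- function(image) {
  if (length(image) < 2) stop("need at least 2 pixels")
  s <- stats::sd(image)
  if (s == 0 || !is.finite(s)) {
    warning("constant image: returning zeros")
    return(array(0, dim = dim(image)))
  }
  array((image - mean(image)) / s, dim = dim(image))
}
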