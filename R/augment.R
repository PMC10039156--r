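## On-the-fly augmentation for image/mask pairs. Each call applies, with a
## configurable probability (default 0.15), one transform drawn from:
## scaling 0.85-1.25x, rotation -15..+15 degrees, vertical/horizontal
## mirroring, elastic deformation (alpha in [0, 900], sigma in [9, 13]) and
## brightness 0.5-2x (image only). Images are resampled bilinearly, masks
## with nearest neighbour so labels stay integral. Geometric warps are
## implemented for 2-D grids; mirroring and brightness also apply to 3-D.

## bilinear / nearest sampling of a 2-D image at fractional (row, col)
## coordinates; out-of-range coordinates take the border value
.sample2d <- function(img, rr, cc, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  rr <- as.vector(pmin(pmax(rr, 1), H))
  cc <- as.vector(pmin(pmax(cc, 1), W))
  if (interp == "nearest") {
    return(matrix(img[cbind(round(rr), round(cc))], H, W))
  }
  r0 <- pmin(floor(rr), H - 1); c0 <- pmin(floor(cc), W - 1)
  fr <- rr - r0; fc <- cc - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  matrix(v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
         v01 * (1 - fr) * fc + v11 * fr * fc, H, W)
}

.warpPair2d <- function(image, mask, srcR, srcC) {
  list(image = .sample2d(image, srcR, srcC, "bilinear"),
       mask = matrix(as.integer(.sample2d(mask + 0, srcR, srcC, "nearest")),
                     nrow(mask), ncol(mask)))
}

.destGrid <- function(H, W) {
  list(r = matrix(rep(seq_len(H), W), H, W),
       c = matrix(rep(seq_len(W), each = H), H, W))
}

## separable Gaussian smoothing with replicated borders
.gaussSmooth2d <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], rad), x, rep(x[n], rad))
    as.numeric(stats::filter(xp, k, sides = 2))[(rad + 1):(rad + n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Apply a named augmentation deterministically
#'
#' The deterministic core behind [augment()]: applies one named transform
#' with explicit parameters to an image/mask pair. The image is resampled
#' bilinearly, the mask with nearest neighbour (labels stay in the original
#' label set). Useful directly when a reproducible transform is wanted.
#'
#' @param image numeric array (2-D for the geometric warps; any rank for
#'   `"mirror"` and `"brightness"`).
#' @param mask matching integer array or [LabelMask-class].
#' @param type one of `"scale"`, `"rotate"`, `"mirror"`, `"elastic"`,
#'   `"brightness"`, `"identity"`.
#' @param params named list of parameters: `factor` (scale), `angle`
#'   (degrees, rotate), `axis` (mirror), `alpha`/`sigma`/`field` (elastic;
#'   `field` is a list of two displacement seeds, optional), `factor`
#'   (brightness).
#' @return `list(image, mask)` with `mask` the same type as supplied.
#' @export
applyAugmentation <- function(image, mask, type, params = list()) {
  mv <- .maskValues(mask)
  wrap <- function(img, m) {
    if (is(mask, "LabelMask")) m <- LabelMask(m, nClasses(mask))
    list(image = img, mask = m)
  }
  if (type == "identity") return(wrap(image, mv))
  if (type == "brightness") {
    f <- params$factor %||% 1
    return(wrap(image * f, mv))
  }
  if (type == "mirror") {
    ax <- params$axis %||% 1L
    d <- dim(image)
    idx <- lapply(seq_along(d), function(a)
      if (a == ax) rev(seq_len(d[a])) else seq_len(d[a]))
    img <- do.call(`[`, c(list(image), idx, list(drop = FALSE)))
    m <- do.call(`[`, c(list(mv), idx, list(drop = FALSE)))
    return(wrap(array(img, d), array(m, d)))
  }
  if (length(dim(image)) != 2)
    stop(sprintf("augmentation '%s' is implemented for 2-D grids only", type))
  H <- nrow(image); W <- ncol(image)
  g <- .destGrid(H, W)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  if (type == "scale") {
    f <- params$factor %||% 1
    srcR <- cr + (g$r - cr) / f
    srcC <- cc + (g$c - cc) / f
  } else if (type == "rotate") {
    th <- (params$angle %||% 0) * pi / 180
    dr <- g$r - cr; dc <- g$c - cc
    srcR <- cr + cos(th) * dr - sin(th) * dc
    srcC <- cc + sin(th) * dr + cos(th) * dc
  } else if (type == "elastic") {
    alpha <- params$alpha %||% 300
    sigma <- params$sigma %||% 10
    if (is.null(params$field)) {
      fr <- matrix(stats::runif(H * W, -1, 1), H, W)
      fc <- matrix(stats::runif(H * W, -1, 1), H, W)
    } else {
      fr <- params$field[[1]]
      fc <- params$field[[2]]
    }
    srcR <- g$r + .gaussSmooth2d(fr, sigma) * alpha
    srcC <- g$c + .gaussSmooth2d(fc, sigma) * alpha
  } else stop(sprintf("unknown augmentation type '%s'", type))
  out <- .warpPair2d(image, mv, srcR, srcC)
  wrap(out$image, out$mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomly augment an image/mask pair
#'
#' With probability `prob` (default 0.15) applies one randomly chosen
#' transform — scaling (0.85-1.25x), rotation (-15 to +15 degrees),
#' vertical or horizontal mirroring, elastic deformation (`alpha` in
#' `[0, 900]`, `sigma` in `[9, 13]`) or brightness (0.5-2x, image only) —
#' otherwise returns the pair unchanged. Uses the caller's RNG stream
#' (seed it for reproducibility). For 3-D inputs only mirroring and
#' brightness are drawn.
#'
#' @param image numeric array.
#' @param mask matching integer array or [LabelMask-class].
#' @param prob probability of applying any augmentation; default 0.15.
#' @return `list(image, mask, transform)`; `transform` names what was
#'   applied (`"identity"` if nothing).
#' @export
augment <- function(image, mask, prob = 0.15) {
  mv <- .maskValues(mask)
  .checkSameShape(image, mv, "image and mask")
  if (stats::runif(1) >= prob) {
    out <- applyAugmentation(image, mask, "identity")
    out$transform <- "identity"
    return(out)
  }
  is2d <- length(dim(image)) == 2
  types <- if (is2d) c("scale", "rotate", "mirror", "mirror", "elastic",
                       "brightness")
           else c("mirror", "brightness")
  type <- sample(types, 1)
  ## the elastic amplitude range is specified for 512-px images; scale the
  ## displacement field with the grid so the relative deformation is
  ## preserved at smaller desk-scale resolutions
  alphaMax <- 900 * min(dim(image)) / 512
  params <- switch(type,
    scale = list(factor = stats::runif(1, 0.85, 1.25)),
    rotate = list(angle = stats::runif(1, -15, 15)),
    mirror = list(axis = sample(seq_along(dim(image)), 1)),
    elastic = list(alpha = stats::runif(1, 0, alphaMax),
                   sigma = stats::runif(1, 9, 13)),
    brightness = list(factor = stats::runif(1, 0.5, 2)))
  out <- applyAugmentation(image, mask, type, params)
  out$transform <- type
  out
}
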