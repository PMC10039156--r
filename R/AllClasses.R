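#' @import methods
NULL

## Central data objects. All pixel containers are dense arrays with the class
## axis last: (H, W, C) for 2-D and (D, H, W, C) for 3-D grids. Class ids are
## zero-based (0 = background), matching the usual segmentation convention.

#' Per-pixel class-probability map
#'
#' An S4 container for softmax-style predictor output: a dense array over
#' (spatial..., class) holding, for every pixel, a probability vector over
#' `C >= 2` classes. Validity enforces entries in `[0, 1]`, finiteness, and
#' per-pixel sums within `1e-6` of 1.
#'
#' @slot values numeric array of rank 3 (H, W, C) or 4 (D, H, W, C).
#' @seealso [ProbabilityMap()], [LabelMask-class], [OneHotMask-class]
#' @export
setClass("ProbabilityMap", representation(values = "array"))

#' Integer label mask
#'
#' Ground-truth (or hard-predicted) per-pixel class labels over a 2-D or 3-D
#' grid. Labels are zero-based class ids in `[0, nClasses - 1]`; the number
#' of classes is carried alongside the array so an all-background mask still
#' knows its label set.
#'
#' @slot values integer array of rank 2 or 3.
#' @slot nClasses integer scalar, number of classes `C >= 2`.
#' @export
setClass("LabelMask", representation(values = "array", nClasses = "integer"))

#' One-hot encoded mask
#'
#' Binary indicator array over (spatial..., class): entry `(i, c)` is 1 iff
#' pixel `i` carries class `c`. Per-pixel sums are exactly 1.
#'
#' @slot values binary numeric array, class axis last.
#' @export
setClass("OneHotMask", representation(values = "array"))

#' Soft and hard confusion aggregates
#'
#' Per-class sums underlying the Dice/Tversky loss family: the soft true
#' positive mass `tp = sum_i p0 * y0`, the gamma-exponentiated soft error
#' sums `fp(gamma) = sum_i (p0 * y1)^gamma` and
#' `fn(gamma) = sum_i (p1 * y0)^gamma`, plus hard TP/FP/FN counts from the
#' argmax-binarised prediction. At `gamma = 1` the soft error sums are the
#' plain false-positive and false-negative probability masses.
#'
#' @slot tpSoft,fpSoft,fnSoft numeric vectors, one entry per class.
#' @slot tpHard,fpHard,fnHard numeric vectors of hard counts per class.
#' @slot gamma the exponent used for `fpSoft`/`fnSoft`.
#' @slot nPixels,nClasses grid size and class count.
#' @export
setClass("ConfusionTerms", representation(
  tpSoft = "numeric", fpSoft = "numeric", fnSoft = "numeric",
  tpHard = "numeric", fpHard = "numeric", fnHard = "numeric",
  gamma = "numeric", nPixels = "integer", nClasses = "integer"))

#' Loss hyperparameter configuration
#'
#' Holds every tunable of the loss family in one object. Defaults are the
#' settings commonly reported as optimal for each loss: Focal
#' `alpha = 0.5, gamma = 2`; Tversky `alpha = 0.3, beta = 0.7`; Focal Tversky
#' adds `gamma = 4/3`; Combo `alpha = beta = 0.5`; Unified Focal
#' `gamma = 0.5, delta = 0.6, lambda = 0.5`. The "++" focal exponent
#' `gammaPP` defaults to 2 and turns any Dice-component loss into its
#' calibration-aware variant; `gammaPP = 1` recovers the original loss.
#'
#' @slot gammaPP focal exponent applied to the soft FP/FN sums (>= 1 in
#'   normal use; values in `[0.5, 1)` are permitted for grid searches, with
#'   a warning).
#' @slot focalAlpha per-class weight(s) for the focal loss (recycled to C).
#' @slot focalGamma focal-loss modulating exponent.
#' @slot tverskyAlpha,tverskyBeta FP and FN weights of the Tversky index.
#' @slot ftGamma focal-Tversky exponent (the loss uses `1/ftGamma`).
#' @slot comboAlpha,comboBeta CE-vs-Dice mixing weight and the positive-class
#'   weight inside the modified CE term.
#' @slot ufLambda,ufDelta,ufGamma unified-focal mixing, asymmetry and focal
#'   parameters (`0 < ufGamma < 1`).
#' @slot rareClass zero-based rare-class id(s) receiving the asymmetric
#'   treatment in the unified focal loss; `NA` means all foreground classes.
#' @slot smoothEps additive smoothing for every ratio numerator/denominator.
#' @slot includeBackground whether class 0 takes part in region-loss
#'   averages.
#' @export
setClass("LossConfig", representation(
  gammaPP = "numeric",
  focalAlpha = "numeric", focalGamma = "numeric",
  tverskyAlpha = "numeric", tverskyBeta = "numeric",
  ftGamma = "numeric",
  comboAlpha = "numeric", comboBeta = "numeric",
  ufLambda = "numeric", ufDelta = "numeric", ufGamma = "numeric",
  rareClass = "numeric",
  smoothEps = "numeric",
  includeBackground = "logical"),
  prototype(
    gammaPP = 2,
    focalAlpha = 0.5, focalGamma = 2,
    tverskyAlpha = 0.3, tverskyBeta = 0.7,
    ftGamma = 4 / 3,
    comboAlpha = 0.5, comboBeta = 0.5,
    ufLambda = 0.5, ufDelta = 0.6, ufGamma = 0.5,
    rareClass = NA_real_,
    smoothEps = 1e-6,
    includeBackground = TRUE))

#' Per-image and aggregate evaluation report
#'
#' One row per image with calibration (NLL, Brier) and overlap (Dice,
#' Jaccard, recall, precision) scores, plus aggregate means and bootstrap
#' standard errors of the mean. Overlap columns are foreground means; the
#' full per-class breakdown is kept in `perClass`.
#'
#' @slot perImage data.frame, one row per image.
#' @slot aggregate,se named numeric vectors (means, bootstrap SEs).
#' @slot perClass list of per-image per-class overlap matrices.
#' @slot nBoot,seed bootstrap replicate count and RNG seed.
#' @export
setClass("MetricReport", representation(
  perImage = "data.frame", aggregate = "numeric", se = "numeric",
  perClass = "list", nBoot = "integer", seed = "integer"))

#' Softmax-threshold sweep result
#'
#' Recall/precision/Dice of the thresholded segmentation as a function of
#' the decision threshold `T` applied to the target-class softmax output,
#' with bootstrap 95% confidence intervals over images.
#'
#' @slot table data.frame with columns `threshold`, `recall`, `precision`,
#'   `dice` and their `*.lo`/`*.hi` confidence bounds.
#' @slot targetClass zero-based class id that was thresholded.
#' @slot nImages number of images aggregated.
#' @export
setClass("ThresholdSweep", representation(
  table = "data.frame", targetClass = "integer", nImages = "integer"))

## ---- validity -------------------------------------------------------------

.checkSpatialRank <- function(r) r %in% c(2L, 3L)

setValidity("ProbabilityMap", function(object) {
  v <- object@values
  d <- dim(v)
  if (is.null(d) || !.checkSpatialRank(length(d) - 1L))
    return("values must have rank 3 (H,W,C) or 4 (D,H,W,C)")
  if (d[length(d)] < 2L) return("need at least 2 classes")
  if (!all(is.finite(v))) return("probabilities must be finite")
  if (min(v) < 0 || max(v) > 1) return("probabilities must lie in [0, 1]")
  s <- .sumOverClasses(v)
  if (max(abs(s - 1)) > 1e-6)
    return(sprintf("per-pixel class sums deviate from 1 by up to %.3g (tolerance 1e-6)",
                   max(abs(s - 1))))
  TRUE
})

setValidity("LabelMask", function(object) {
  v <- object@values
  d <- dim(v)
  if (is.null(d) || !.checkSpatialRank(length(d)))
    return("values must have spatial rank 2 or 3")
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    return("nClasses must be a single integer >= 2")
  if (any(v != round(v)) || min(v) < 0)
    return("labels must be non-negative integers")
  if (max(v) >= object@nClasses)
    return(sprintf("invalid label %d: labels must be < nClasses = %d",
                   max(v), object@nClasses))
  TRUE
})

setValidity("OneHotMask", function(object) {
  v <- object@values
  d <- dim(v)
  if (is.null(d) || !.checkSpatialRank(length(d) - 1L))
    return("values must have rank 3 or 4 with the class axis last")
  if (!all(v %in% c(0, 1))) return("entries must be 0 or 1")
  if (any(.sumOverClasses(v) != 1)) return("per-pixel sums must equal exactly 1")
  TRUE
})

setValidity("ConfusionTerms", function(object) {
  lens <- c(length(object@tpSoft), length(object@fpSoft), length(object@fnSoft),
            length(object@tpHard), length(object@fpHard), length(object@fnHard))
  if (length(unique(lens)) != 1L || lens[1] != object@nClasses)
    return("per-class slots must all have length nClasses")
  if (min(object@tpSoft, object@fpSoft, object@fnSoft,
          object@tpHard, object@fpHard, object@fnHard) < 0)
    return("confusion aggregates must be non-negative")
  TRUE
})

setValidity("LossConfig", function(object) {
  scalars <- c("gammaPP", "focalGamma", "tverskyAlpha", "tverskyBeta",
               "ftGamma", "comboAlpha", "comboBeta", "ufLambda", "ufDelta",
               "ufGamma", "smoothEps")
  for (s in scalars)
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a finite scalar", s))
  if (object@gammaPP <= 0) return("gammaPP must be positive")
  if (object@focalGamma < 0) return("focalGamma must be >= 0")
  if (object@tverskyAlpha < 0 || object@tverskyBeta < 0)
    return("tverskyAlpha and tverskyBeta must be >= 0")
  if (object@ftGamma <= 0) return("ftGamma must be > 0")
  if (object@comboAlpha < 0 || object@comboAlpha > 1 ||
      object@comboBeta < 0 || object@comboBeta > 1)
    return("comboAlpha and comboBeta must lie in [0, 1]")
  if (object@ufLambda < 0 || object@ufLambda > 1 ||
      object@ufDelta < 0 || object@ufDelta > 1)
    return("ufLambda and ufDelta must lie in [0, 1]")
  if (object@ufGamma <= 0 || object@ufGamma >= 1)
    return("ufGamma must lie strictly in (0, 1)")
  if (object@smoothEps <= 0) return("smoothEps must be positive")
  TRUE
})

## ---- constructors ---------------------------------------------------------

#' Create a ProbabilityMap
#'
#' @param values numeric array over (spatial..., class), class axis last.
#' @param renormalise if `TRUE`, per-pixel sums are rescaled to 1 before
#'   validation (never done silently otherwise).
#' @return A [ProbabilityMap-class] object.
#' @examples
#' p <- array(0.5, dim = c(2, 2, 2))
#' ProbabilityMap(p)
#' @export
ProbabilityMap <- function(values, renormalise = FALSE) {
  values <- .asNumericArray(values)
  if (renormalise) {
    s <- .sumOverClasses(values)
    values <- values / .expandOverClasses(s, dim(values))
  }
  new("ProbabilityMap", values = values)
}

#' Create a LabelMask
#'
#' @param values integer array of zero-based class labels, spatial rank 2
#'   or 3.
#' @param nClasses number of classes; defaults to `max(values) + 1` (at
#'   least 2).
#' @return A [LabelMask-class] object.
#' @examples
#' LabelMask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
#' @export
LabelMask <- function(values, nClasses = NULL) {
  if (is.null(dim(values))) stop("mask must be an array of rank 2 or 3")
  if (is.null(nClasses)) nClasses <- max(2, max(values) + 1)
  storage.mode(values) <- "integer"
  new("LabelMask", values = values, nClasses = as.integer(nClasses))
}

#' Create a OneHotMask
#'
#' @param values binary array over (spatial..., class).
#' @return A [OneHotMask-class] object.
#' @export
OneHotMask <- function(values) {
  new("OneHotMask", values = .asNumericArray(values))
}

#' Create a LossConfig
#'
#' All arguments default to the standard settings documented in
#' [LossConfig-class]; pass only what you want to change.
#'
#' @param ... named slot values, e.g. `gammaPP = 2`, `tverskyAlpha = 0.3`.
#' @return A [LossConfig-class] object.
#' @examples
#' cfg <- LossConfig(gammaPP = 1.5, includeBackground = FALSE)
#' gammaPP(cfg)
#' @export
LossConfig <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), slotNames("LossConfig"))
  if (length(bad)) stop("unknown LossConfig field(s): ", paste(bad, collapse = ", "))
  do.call(new, c(list("LossConfig"), args))
}

## ---- accessors ------------------------------------------------------------

#' @rdname ProbabilityMap
#' @param x an object with a `values` slot.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname ProbabilityMap
#' @export
setMethod("values", "ProbabilityMap", function(x) x@values)
#' @rdname ProbabilityMap
#' @export
setMethod("values", "LabelMask", function(x) x@values)
#' @rdname ProbabilityMap
#' @export
setMethod("values", "OneHotMask", function(x) x@values)

#' Number of classes of a segmentation object
#' @param x a ProbabilityMap, LabelMask or OneHotMask.
#' @return integer class count.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
#' @rdname nClasses
#' @export
setMethod("nClasses", "ProbabilityMap", function(x) dim(x@values)[length(dim(x@values))])
#' @rdname nClasses
#' @export
setMethod("nClasses", "LabelMask", function(x) as.integer(x@nClasses))
#' @rdname nClasses
#' @export
setMethod("nClasses", "OneHotMask", function(x) dim(x@values)[length(dim(x@values))])

#' The "++" focal exponent of a LossConfig
#' @param x a [LossConfig-class].
#' @return numeric scalar.
#' @export
gammaPP <- function(x) x@gammaPP

#' Per-image metric table of a MetricReport
#' @param x a [MetricReport-class].
#' @return data.frame with one row per image.
#' @export
perImage <- function(x) x@perImage

#' Aggregate means of a MetricReport
#' @param x a [MetricReport-class].
#' @return named numeric vector of metric means.
#' @export
aggregateMetrics <- function(x) x@aggregate

#' Bootstrap standard errors of a MetricReport
#' @param x a [MetricReport-class].
#' @return named numeric vector of SEs.
#' @export
standardErrors <- function(x) x@se

#' Result table of a ThresholdSweep
#' @param x a [ThresholdSweep-class].
#' @return data.frame of per-threshold metrics with confidence bounds.
#' @export
sweepTable <- function(x) x@table

## ---- show methods ---------------------------------------------------------

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMap: %s grid, %d classes\n",
              paste(d[-length(d)], collapse = " x "), d[length(d)]))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@values)
  tab <- table(object@values)
  cat(sprintf("LabelMask: %s grid, %d classes; foreground fraction %.4f\n",
              paste(d, collapse = " x "), object@nClasses,
              mean(object@values != 0)))
})

setMethod("show", "OneHotMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("OneHotMask: %s grid, %d classes\n",
              paste(d[-length(d)], collapse = " x "), d[length(d)]))
})

setMethod("show", "ConfusionTerms", function(object) {
  cat(sprintf("ConfusionTerms (gamma = %g, N = %d, C = %d)\n",
              object@gamma, object@nPixels, object@nClasses))
  print(data.frame(class = seq_len(object@nClasses) - 1L,
                   tpSoft = object@tpSoft, fpSoft = object@fpSoft,
                   fnSoft = object@fnSoft, TP = object@tpHard,
                   FP = object@fpHard, FN = object@fnHard))
})

setMethod("show", "LossConfig", function(object) {
  cat("LossConfig:\n")
  for (s in slotNames("LossConfig"))
    cat(sprintf("  %-18s %s\n", s, paste(format(slot(object, s)), collapse = ", ")))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d image(s), %d bootstrap replicates\n",
              nrow(object@perImage), object@nBoot))
  agg <- rbind(mean = object@aggregate, se = object@se[names(object@aggregate)])
  print(round(agg, 4))
})

setMethod("show", "ThresholdSweep", function(object) {
  cat(sprintf("ThresholdSweep: class %d, %d thresholds, %d image(s)\n",
              object@targetClass, nrow(object@table), object@nImages))
  print(utils::head(object@table, 4))
  if (nrow(object@table) > 4) cat("  ...\n")
})
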