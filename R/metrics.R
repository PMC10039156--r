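## Calibration (NLL, Brier) and overlap (Dice, Jaccard, recall, precision)
## evaluation, with bootstrap standard errors over images.

#' Negative log likelihood
#'
#' NLL of the true labels under the predicted probabilities. Identical in
#' form to the cross-entropy loss and shares its implementation, so the two
#' agree to the last bit.
#'
#' @inheritParams ceLoss
#' @return Non-negative numeric scalar (lower is better calibrated).
#' @export
nll <- function(p, y) as.numeric(ceLoss(p, y))

#' Brier score
#'
#' Mean squared error between the predicted probability vectors and the
#' one-hot truth, `(1/C)(1/N) sum_c sum_i (y - p)^2`. A strictly proper
#' scoring rule; 0 for a perfect prediction, bounded by 1.
#'
#' @inheritParams ceLoss
#' @return Numeric scalar in `[0, 1]` (lower is better calibrated).
#' @examples
#' y <- oneHotEncode(LabelMask(matrix(c(0L, 1L), 1, 2)))
#' p <- array(c(0.9, 0.4, 0.1, 0.6), dim = c(1, 2, 2))
#' brier(p, y)  # 0.085
#' @export
brier <- function(p, y) {
  pv <- .probArray(p)
  yv <- .onehotArray(y)
  .checkSameShape(pv, yv, "probability map and one-hot mask")
  mean((yv - pv)^2)
}

.hardCounts <- function(pred, truth, nClasses) {
  counts <- matrix(0, nClasses, 3, dimnames = list(NULL, c("TP", "FP", "FN")))
  for (c in seq_len(nClasses)) {
    pc <- pred == (c - 1L)
    tc <- truth == (c - 1L)
    counts[c, ] <- c(sum(pc & tc), sum(pc & !tc), sum(!pc & tc))
  }
  counts
}

.metricsFromCounts <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  ## empty-class convention: a correctly-empty class scores 1
  safe <- function(num, den) ifelse(den == 0, 1, num / den)
  c(dice = safe(2 * tp, 2 * tp + fp + fn),
    jaccard = safe(tp, tp + fp + fn),
    recall = safe(tp, tp + fn),
    precision = safe(tp, tp + fp))
}

#' Hard overlap metrics from label masks
#'
#' Per-class Dice, Jaccard, recall and precision from hard TP/FP/FN counts:
#' `dice = 2TP/(2TP+FP+FN)`, `jaccard = TP/(TP+FP+FN)`,
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`. A class absent from
#' both masks (TP = FP = FN = 0) scores 1 by convention. The foreground
#' mean (classes `>= 1`) is reported alongside the per-class values.
#'
#' @param pred,truth [LabelMask-class] objects or integer arrays of the
#'   same shape.
#' @param nClasses number of classes.
#' @return A list with `perClass` (nClasses x 4 matrix) and `mean`
#'   (named vector, foreground mean).
#' @export
hardOverlapMetrics <- function(pred, truth, nClasses = NULL) {
  pv <- .maskValues(pred)
  tv <- .maskValues(truth)
  .checkSameShape(pv, tv, "prediction and truth masks")
  if (is.null(nClasses)) {
    nClasses <- max(2,
                    if (is(pred, "LabelMask")) nClasses(pred) else max(pv) + 1,
                    if (is(truth, "LabelMask")) nClasses(truth) else max(tv) + 1)
  }
  counts <- .hardCounts(pv, tv, nClasses)
  perClass <- t(apply(counts, 1, function(r) .metricsFromCounts(r[1], r[2], r[3])))
  rownames(perClass) <- paste0("class", seq_len(nClasses) - 1L)
  list(perClass = perClass,
       mean = colMeans(perClass[-1, , drop = FALSE]))
}

## Run expr with a private, seeded RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bootstrap standard error of the mean
#'
#' Standard deviation of the mean over `nBoot` resamples (with replacement,
#' resample size equal to the number of values). Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param x numeric vector of per-image values (length >= 2).
#' @param nBoot number of bootstrap replicates (>= 100); default 1000.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return Numeric scalar standard error.
#' @examples
#' bootstrapSE(rep(c(0, 1), 50), nBoot = 1000, seed = 1)  # about 0.05
#' @export
bootstrapSE <- function(x, nBoot = 1000, seed) {
  if (length(x) < 2) stop("insufficient data: need at least 2 values")
  if (nBoot < 100) stop("nBoot must be >= 100")
  if (missing(seed)) stop("seed is mandatory")
  n <- length(x)
  .withSeed(seed, {
    means <- vapply(seq_len(nBoot),
                    function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    stats::sd(means)
  })
}

#' Evaluate a set of predictions against ground truth
#'
#' Computes per-image NLL, Brier, and foreground-mean Dice, Jaccard, recall
#' and precision (overlap metrics from the argmax-binarised prediction),
#' then aggregates as arithmetic means with bootstrap standard errors of
#' the mean. Mirrors the tabular layout used to compare loss functions:
#' calibration columns alongside performance columns.
#'
#' @param preds list of [ProbabilityMap-class] objects (or arrays).
#' @param truths list of [LabelMask-class] objects (or integer arrays).
#' @param nBoot bootstrap replicates for the SEs; default 1000.
#' @param seed integer RNG seed for the bootstrap.
#' @param ids optional image identifiers (default `img1`, `img2`, ...).
#' @return A [MetricReport-class] object.
#' @export
evaluateDataset <- function(preds, truths, nBoot = 1000, seed = 1,
                            ids = NULL) {
  if (length(preds) != length(truths))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(preds), length(truths)))
  n <- length(preds)
  if (n == 0) stop("empty dataset")
  if (is.null(ids)) ids <- paste0("img", seq_len(n))
  perClass <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pv <- .probArray(preds[[i]])
    tv <- .maskValues(truths[[i]])
    C <- dim(pv)[length(dim(pv))]
    yv <- oneHotEncode(tv, C)
    pred <- values(decodeLabels(pv))
    ov <- hardOverlapMetrics(pred, tv, C)
    perClass[[i]] <- ov$perClass
    rows[[i]] <- data.frame(id = ids[i], nll = nll(pv, yv),
                            brier = brier(pv, yv),
                            dice = ov$mean["dice"], jaccard = ov$mean["jaccard"],
                            recall = ov$mean["recall"],
                            precision = ov$mean["precision"],
                            row.names = NULL)
  }
  perImage <- do.call(rbind, rows)
  metricCols <- c("nll", "brier", "dice", "jaccard", "recall", "precision")
  agg <- vapply(perImage[metricCols], mean, numeric(1))
  se <- if (n >= 2) {
    vapply(seq_along(metricCols), function(k)
      bootstrapSE(perImage[[metricCols[k]]], nBoot, seed + k - 1L), numeric(1))
  } else rep(NA_real_, length(metricCols))
  names(se) <- metricCols
  new("MetricReport", perImage = perImage, aggregate = agg, se = se,
      perClass = perClass, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Write a MetricReport to CSV / JSON
#'
#' `writeMetricReport` writes the per-image table as CSV (fixed header:
#' id, nll, brier, dice, jaccard, recall, precision) and, optionally, the
#' aggregate means and standard errors as JSON.
#'
#' @param report a [MetricReport-class].
#' @param csv path for the per-image CSV (or `NULL` to skip).
#' @param json path for the aggregate JSON summary (or `NULL` to skip).
#' @return Invisibly, the report.
#' @export
writeMetricReport <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(perImage(report), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(aggregate = as.list(report@aggregate),
                              se = as.list(report@se),
                              nBoot = report@nBoot, seed = report@seed),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
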