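## Softmax-threshold post-processing: replace the argmax decision with a
## tunable cutoff T on the target-class softmax output, trading recall
## against precision after training.

#' Threshold a probability map into a label mask
#'
#' Labels a pixel as the target class iff its target-class softmax output
#' `s` satisfies `s >= T`, and background otherwise (one-vs-rest for the
#' named class). For a binary map, `T = 0.5` reproduces the per-pixel
#' argmax (ties at `s == T` go to the target class, matching the
#' lowest-index argmax convention only off ties). Higher thresholds shrink
#' the predicted-positive set, favouring precision; lower thresholds
#' favour recall.
#'
#' @param p a [ProbabilityMap-class] or probability array.
#' @param targetClass zero-based class id to threshold; default 1
#'   (first foreground class).
#' @param threshold decision threshold `T` in `(0, 1)`.
#' @return A [LabelMask-class]: pixels are `targetClass` or 0.
#' @examples
#' p <- array(c(0.6, 0.4, 0.4, 0.6), dim = c(1, 2, 2))
#' values(applyThreshold(p, 1, 0.5))
#' values(applyThreshold(p, 1, 0.7))
#' @export
applyThreshold <- function(p, targetClass = 1L, threshold = 0.5) {
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  pv <- .probArray(p)
  d <- dim(pv)
  C <- d[length(d)]
  if (targetClass < 0 || targetClass > C - 1)
    stop(sprintf("targetClass must lie in [0, %d]", C - 1))
  s <- .pixelMatrix(pv)[, targetClass + 1L]
  lab <- array(ifelse(s >= threshold, as.integer(targetClass), 0L),
               dim = d[-length(d)])
  LabelMask(lab, nClasses = C)
}

#' Recall-precision sweep over softmax thresholds
#'
#' For each threshold `T`, binarises every prediction with
#' [applyThreshold()], scores the target class against the truth with hard
#' overlap metrics, and aggregates over images (means with bootstrap 95%
#' confidence intervals). Because the predicted-positive set shrinks
#' monotonically in `T`, recall is non-increasing and false positives
#' non-increasing across the sweep.
#'
#' @param preds list of [ProbabilityMap-class] objects (or arrays).
#' @param truths list of [LabelMask-class] objects (or integer arrays).
#' @param thresholds strictly increasing vector in `(0, 1)`; default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @param targetClass zero-based class id; default 1.
#' @param nBoot bootstrap replicates for the confidence intervals.
#' @param seed RNG seed for the bootstrap.
#' @return A [ThresholdSweep-class] object.
#' @export
thresholdSweep <- function(preds, truths,
                           thresholds = seq(0.05, 0.95, by = 0.05),
                           targetClass = 1L, nBoot = 1000, seed = 1) {
  if (length(thresholds) == 0) stop("empty threshold list")
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (length(preds) != length(truths))
    stop("length mismatch between predictions and truths")
  n <- length(preds)
  tc <- as.integer(targetClass)
  rowFor <- function(T) {
    per <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("recall", "precision", "dice")))
    for (i in seq_len(n)) {
      pred <- values(applyThreshold(preds[[i]], tc, T))
      truth <- .maskValues(truths[[i]])
      ## one-vs-rest on the target class
      m <- hardOverlapMetrics(1L * (pred == tc), 1L * (truth == tc), 2L)
      per[i, ] <- m$perClass[2, c("recall", "precision", "dice")]
    }
    ci <- function(v, k) {
      if (n < 2) return(c(NA_real_, NA_real_))
      .withSeed(seed + k, {
        means <- vapply(seq_len(nBoot),
                        function(j) mean(v[sample.int(n, n, replace = TRUE)]),
                        numeric(1))
        stats::quantile(means, c(0.025, 0.975), names = FALSE)
      })
    }
    ciR <- ci(per[, "recall"], 1L); ciP <- ci(per[, "precision"], 2L)
    ciD <- ci(per[, "dice"], 3L)
    data.frame(threshold = T,
               recall = mean(per[, "recall"]),
               recall.lo = ciR[1], recall.hi = ciR[2],
               precision = mean(per[, "precision"]),
               precision.lo = ciP[1], precision.hi = ciP[2],
               dice = mean(per[, "dice"]),
               dice.lo = ciD[1], dice.hi = ciD[2])
  }
  tab <- do.call(rbind, lapply(thresholds, rowFor))
  new("ThresholdSweep", table = tab, targetClass = tc,
      nImages = as.integer(n))
}
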