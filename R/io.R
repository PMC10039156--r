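## Readers/writers for images, label masks and probability maps, plus the
## dataset manifest. On-disk conventions: PNG/TIFF for 2-D, NIfTI for 3-D;
## probability maps store the class axis last (multi-page float TIFF in
## 2-D, 4-D NIfTI in 3-D). Greyscale masks are mapped to dense labels
## 0..C-1 by sorted unique values, with the mapping logged.

.fileExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

.checkFileExists <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  invisible(path)
}

#' Read an image file
#'
#' Reads PNG or TIFF (2-D) or NIfTI (3-D) into a numeric array. Colour PNGs
#' are collapsed to greyscale by channel averaging.
#'
#' @param path input file path.
#' @return Numeric array.
#' @export
readImageFile <- function(path) {
  .checkFileExists(path)
  ext <- .fileExt(path)
  v <- switch(ext,
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
      img
    },
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = ,
    "nii.gz" = {
      im <- RNifti::readNifti(path)
      array(as.numeric(im), dim = dim(im))
    },
    stop(sprintf("unknown image format '%s' (expected png/tif/tiff/nii)", ext)))
  storage.mode(v) <- "double"
  v
}

#' Write an image file
#'
#' PNG/TIFF values are clipped to `[0, 1]`; NIfTI stores the raw values.
#'
#' @param image numeric array.
#' @param path output path (extension selects the format).
#' @return Invisibly, `path`.
#' @export
writeImageFile <- function(image, path) {
  ext <- .fileExt(path)
  switch(ext,
    png = png::writePNG(pmin(pmax(image, 0), 1), path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(image, 0), 1), path,
                           bits.per.sample = 16L),
    nii = ,
    "nii.gz" = RNifti::writeNifti(RNifti::asNifti(image, datatype = "double"), path),
    stop(sprintf("unknown image format '%s'", ext)))
  invisible(path)
}

#' Read a label mask
#'
#' Greyscale PNG/TIFF values are rescaled to integers and mapped to dense
#' labels `0..C-1` by sorted unique value (the mapping is logged via
#' `message()`); NIfTI masks must already hold integral values.
#'
#' @param path input file path.
#' @param nClasses optional class count for the resulting
#'   [LabelMask-class].
#' @return A [LabelMask-class].
#' @export
readMask <- function(path, nClasses = NULL) {
  .checkFileExists(path)
  ext <- .fileExt(path)
  raw <- readImageFile(path)
  v <- if (ext %in% c("png", "tif", "tiff")) round(raw * 255) else raw
  if (any(v != round(v)))
    stop(sprintf("non-integral mask values in %s", path))
  u <- sort(unique(as.vector(v)))
  lab <- array(match(v, u) - 1L, dim = dim(v))
  if (!identical(as.numeric(u), as.numeric(seq_along(u) - 1)))
    message(sprintf("mask %s: mapped values {%s} -> labels {%s}",
                    basename(path), paste(u, collapse = ","),
                    paste(seq_along(u) - 1L, collapse = ",")))
  LabelMask(lab, nClasses = if (is.null(nClasses)) max(2, length(u)) else nClasses)
}

#' Write a label mask
#'
#' PNG/TIFF store `label / 255` grey levels (so labels survive a round
#' trip); NIfTI stores the integer labels directly.
#'
#' @param mask a [LabelMask-class] or integer array.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  v <- .maskValues(mask)
  ext <- .fileExt(path)
  switch(ext,
    png = png::writePNG(v / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(v / 255, path, bits.per.sample = 8L),
    nii = ,
    "nii.gz" = RNifti::writeNifti(RNifti::asNifti(v + 0L, datatype = "int16"), path),
    stop(sprintf("unknown mask format '%s'", ext)))
  invisible(path)
}

#' Read / write probability maps
#'
#' 2-D maps are stored as multi-page 32-bit float TIFF (one page per class;
#' float32 precision); 3-D maps as 4-D NIfTI with the class axis fourth and
#' double precision (bitwise-lossless round trip). Maps are validated on
#' read; per-pixel class sums deviating from 1 by more than `1e-6` raise an
#' error unless `renormalise = TRUE`.
#'
#' @param path file path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param renormalise rescale per-pixel sums to 1 instead of erroring.
#' @return `readProbMap`: a [ProbabilityMap-class].
#' @export
readProbMap <- function(path, renormalise = FALSE) {
  .checkFileExists(path)
  ext <- .fileExt(path)
  v <- switch(ext,
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    },
    nii = ,
    "nii.gz" = {
      im <- RNifti::readNifti(path)
      array(as.numeric(im), dim = dim(im))
    },
    stop(sprintf("unknown probability-map format '%s'", ext)))
  ProbabilityMap(v, renormalise = renormalise)
}

#' @rdname readProbMap
#' @param p a [ProbabilityMap-class] or probability array.
#' @export
writeProbMap <- function(p, path) {
  v <- .probArray(p)
  d <- dim(v)
  ext <- .fileExt(path)
  if (ext %in% c("tif", "tiff")) {
    if (length(d) != 3)
      stop("TIFF probability maps must be 2-D (H, W, C); use NIfTI for 3-D")
    pages <- lapply(seq_len(d[3]), function(c) v[, , c])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext %in% c("nii", "nii.gz")) {
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "double"), path)
  } else stop(sprintf("unknown probability-map format '%s'", ext))
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns `image`, `mask`, optional `probmap`
#' and optional `split`; paths are resolved relative to the manifest's
#' directory and checked for existence at load time.
#'
#' @param path manifest CSV path.
#' @return `readManifest`: a data.frame with absolute paths.
#' @export
readManifest <- function(path) {
  .checkFileExists(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(df)))
    stop("manifest must have 'image' and 'mask' columns")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "" | is.na(p), NA_character_,
                                file.path(base, p))
  for (col in intersect(c("image", "mask", "probmap"), names(df))) {
    df[[col]] <- resolve(df[[col]])
    for (f in stats::na.omit(df[[col]])) .checkFileExists(f)
  }
  df
}

#' @rdname readManifest
#' @param manifest data.frame with relative paths.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
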