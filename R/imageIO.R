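#' Mask a slice and crop it to the mask's bounding box
#'
#' Restricts an intensity image to the tight bounding box of a binary tumor
#' mask. Pixels outside the mask are set to 0; foreground intensities are
#' preserved. Any nonzero mask value counts as foreground.
#'
#' @param image numeric matrix of intensities.
#' @param mask matrix of the same dimensions; nonzero marks the ROI.
#' @return numeric matrix covering the mask bounding box, zero outside the
#'   mask.
#' @examples
#' img <- matrix(7, 4, 4)
#' msk <- matrix(0, 4, 4); msk[2:3, 2:3] <- 1
#' applyMaskAndCrop(img, msk)  # 2x2 matrix of 7s
#' @export
applyMaskAndCrop <- function(image, mask) {
  stopifnot(is.matrix(image), is.matrix(mask))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  if (!all(is.finite(image)))
    stop("image contains non-finite pixel values")
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("empty ROI: mask has no foreground pixels")
  r <- range(fg[, 1L]); c <- range(fg[, 2L])
  out <- image[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE] *
    (mask[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE] != 0)
  out
}

#' Z-score-normalize a masked slice
#'
#' Replaces each foreground pixel X by (X - mu) / sigma, where mu and sigma
#' are the mean and standard deviation of the foreground intensities; the
#' background stays exactly 0. By default sigma is the sample standard
#' deviation (denominator n - 1, the convention of common scientific
#' computing environments); the population form (denominator n) is
#' available. The choice only rescales the ROI by sqrt(n/(n-1)) and does not
#' affect any scale-invariant downstream quantity.
#'
#' @param image numeric matrix.
#' @param mask matrix of the same dimensions; nonzero marks the foreground.
#'   If missing, all nonzero pixels of \code{image} are treated as foreground
#'   (appropriate after [applyMaskAndCrop()]).
#' @param sdType \code{"sample"} (default, divide by n - 1) or
#'   \code{"population"} (divide by n).
#' @return numeric matrix; foreground mean 0 and standard deviation 1
#'   (of the chosen type), background 0.
#' @export
zscoreNormalize <- function(image, mask = NULL,
                            sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- image != 0
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  fg <- mask != 0
  n <- sum(fg)
  if (n < 2L)
    stop("need at least 2 foreground pixels to normalize")
  v <- image[fg]
  mu <- mean(v)
  ss <- sum((v - mu)^2)
  sigma <- sqrt(ss / if (sdType == "population") n else (n - 1L))
  if (sigma <= 0)
    stop("degenerate intensity: constant ROI has zero standard deviation")
  out <- matrix(0, nrow(image), ncol(image))
  out[fg] <- (v - mu) / sigma
  out
}

## centered zero-padding of a matrix to target dimensions
.padCenter <- function(m, M, N) {
  dm <- dim(m)
  if (dm[1L] > M || dm[2L] > N) stop("cannot pad to smaller dimensions")
  out <- matrix(0, M, N)
  r0 <- floor((M - dm[1L]) / 2)
  c0 <- floor((N - dm[2L]) / 2)
  out[(r0 + 1L):(r0 + dm[1L]), (c0 + 1L):(c0 + dm[2L])] <- m
  out
}

#' Assemble a normalized 3-slice tumor stack
#'
#' Applies the per-slice ROI workflow -- mask, crop to the mask bounding box,
#' z-score-normalize over the foreground -- and pads all three results with
#' zeros (centered) to the maximum bounding-box height and width across the
#' stack, so consecutive slices have compatible dimensions for
#' cross-correlation.
#'
#' @param slices list of exactly 3 intensity matrices.
#' @param masks list of 3 binary mask matrices, shapes matching
#'   \code{slices}.
#' @param label \code{"co-deleted"} or \code{"non-deleted"}.
#' @param contrast imaging contrast tag, e.g. \code{"T1C"} or \code{"T2W"}.
#' @param subjectID subject identifier string.
#' @param grade tumor grade string (\code{"G-II"} or \code{"G-III"}).
#' @param sdType passed to [zscoreNormalize()].
#' @return a validated [GliomaStack-class] object.
#' @export
assembleStack <- function(slices, masks, label, contrast,
                          subjectID = "subject", grade = "G-II",
                          sdType = "sample") {
  if (length(slices) != 3L || length(masks) != 3L)
    stop("exactly 3 slice/mask pairs are required, got ",
         length(slices), "/", length(masks))
  proc <- vector("list", 3L)
  for (i in 1:3) {
    proc[[i]] <- tryCatch({
      cropped <- applyMaskAndCrop(slices[[i]], masks[[i]])
      croppedMask <- applyMaskAndCrop(masks[[i]], masks[[i]])
      ## the cropped mask, not nonzero-ness, defines the foreground: a valid
      ## in-mask intensity may be exactly 0
      zscoreNormalize(cropped, croppedMask, sdType = sdType)
    }, error = function(e) stop("slice ", i, ": ", conditionMessage(e),
                                call. = FALSE))
  }
  M <- max(vapply(proc, nrow, integer(1L)))
  N <- max(vapply(proc, ncol, integer(1L)))
  proc <- lapply(proc, .padCenter, M = M, N = N)
  new("GliomaStack", slices = proc, label = label, contrast = contrast,
      subjectID = as.character(subjectID), grade = as.character(grade))
}

.manifestCols <- c("subject_id", "grade", "contrast", "label",
                   paste0("slice", 1:3), paste0("mask", 1:3))

#' Read a cohort manifest table
#'
#' The manifest is a CSV with one row per subject per contrast and columns
#' \code{subject_id, grade, contrast, label, slice1..slice3, mask1..mask3}
#' (the last six holding file paths, relative to \code{dirname(path)} unless
#' absolute).
#'
#' @param path path to the manifest CSV.
#' @return data.frame with the validated manifest plus an attribute
#'   \code{baseDir} used to resolve relative paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.manifestCols, names(man))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  bad <- !man$label %in% c("co-deleted", "non-deleted")
  if (any(bad))
    stop("unrecognized labels in manifest: ",
         paste(unique(man$label[bad]), collapse = ", "))
  attr(man, "baseDir") <- dirname(normalizePath(path))
  man
}

.resolvePath <- function(p, baseDir) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(baseDir, p)
}

.readSlicePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]  # grayscale stored with channels
  a
}

#' Read and assemble one subject's stack from manifest files
#'
#' @param row one row of a manifest data.frame (see [readManifest()]).
#' @param baseDir directory against which relative paths are resolved;
#'   defaults to the manifest's \code{baseDir} attribute when \code{row}
#'   retains it.
#' @param sdType passed to [assembleStack()].
#' @return a [GliomaStack-class].
#' @export
readSubjectStack <- function(row, baseDir = NULL, sdType = "sample") {
  if (is.null(baseDir)) baseDir <- attr(row, "baseDir")
  if (is.null(baseDir)) baseDir <- "."
  slices <- lapply(1:3, function(i)
    .readSlicePNG(.resolvePath(row[[paste0("slice", i)]], baseDir)))
  masks <- lapply(1:3, function(i)
    1 * (.readSlicePNG(.resolvePath(row[[paste0("mask", i)]], baseDir)) > 0))
  assembleStack(slices, masks, label = row$label, contrast = row$contrast,
                subjectID = row$subject_id, grade = row$grade,
                sdType = sdType)
}

#' Read a 3-slice stack from a NIfTI volume and mask
#'
#' Extracts three consecutive axial slices from a NIfTI intensity volume and
#' a matching mask volume and assembles them into a normalized stack.
#' Requires the RNifti package.
#'
#' @param volumePath,maskPath paths to NIfTI files of identical dimensions.
#' @param sliceIndices integer vector of 3 consecutive slice indices along
#'   the third axis.
#' @param ... metadata passed to [assembleStack()] (\code{label},
#'   \code{contrast}, \code{subjectID}, \code{grade}).
#' @return a [GliomaStack-class].
#' @export
readNiftiStack <- function(volumePath, maskPath, sliceIndices, ...) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("readNiftiStack requires the RNifti package")
  if (length(sliceIndices) != 3L || any(diff(sliceIndices) != 1L))
    stop("sliceIndices must be 3 consecutive integers")
  vol <- as.array(RNifti::readNifti(volumePath))
  msk <- as.array(RNifti::readNifti(maskPath))
  if (!identical(dim(vol), dim(msk)))
    stop("volume and mask dimensions differ")
  slices <- lapply(sliceIndices, function(k) vol[, , k])
  masks <- lapply(sliceIndices, function(k) 1 * (msk[, , k] > 0))
  assembleStack(slices, masks, ...)
}
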