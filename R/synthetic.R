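#' Configuration for the synthetic phantom cohort generator
#'
#' Phantoms emulate the cohort structure the classifier is designed for:
#' two classes at roughly 2:1 imbalance, each subject contributing a stack
#' of 3 consecutive slices per imaging contrast. Class identity is encoded
#' purely as across-slice texture consistency: co-deleted-like subjects
#' share one base texture across the 3 slices plus independent per-slice
#' texture jitter of standard deviation \code{sliceNoiseSD} (drawn with the
#' same correlation length, so growing \code{sliceNoiseSD} interpolates
#' continuously toward fully independent slices); non-deleted-like subjects
#' get 3 independently drawn textures. Textures are smoothed Gaussian random
#' fields, not simulated MRI physics; the method consumes only relative
#' across-slice consistency, which this controls directly.
#'
#' @param nCodeleted,nNondeleted subject counts per class (>= 0).
#' @param roiSize integer c(height, width) of the phantom image, >= 8 each.
#' @param contrasts named numeric vector mapping contrast tags to texture
#'   correlation lengths in pixels; each contrast is an independent draw.
#' @param sliceNoiseSD standard deviation of the per-slice noise added to
#'   co-deleted-like stacks, relative to unit texture standard deviation
#'   (>= 0). Default 0.1: strongly consistent across-slice texture.
#' @param maskEllipticity ratio of the elliptical mask's column semi-axis to
#'   its row semi-axis (in units of the respective image dimension).
#' @param gradeFractionGII fraction of subjects per class tagged "G-II"
#'   (the rest "G-III"); metadata only.
#' @param nullEffect if TRUE, co-deleted-like subjects ALSO get independent
#'   textures, removing the class signal entirely (calibration runs).
#' @param seed master integer seed; per-subject seeds are derived from it
#'   reproducibly.
#' @return validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(nCodeleted, nNondeleted, roiSize = c(64L, 64L),
                          contrasts = c(T1C = 3, T2W = 5),
                          sliceNoiseSD = 0.1, maskEllipticity = 0.75,
                          gradeFractionGII = 0.65, nullEffect = FALSE,
                          seed = 1L) {
  if (nCodeleted < 0 || nNondeleted < 0) stop("subject counts must be >= 0")
  if (length(roiSize) != 2L || any(roiSize < 8L))
    stop("roiSize must be at least 8 x 8")
  if (sliceNoiseSD < 0) stop("sliceNoiseSD must be >= 0")
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    stop("contrasts must be a named vector of correlation lengths")
  if (maskEllipticity <= 0) stop("maskEllipticity must be positive")
  cfg <- list(nCodeleted = as.integer(nCodeleted),
              nNondeleted = as.integer(nNondeleted),
              roiSize = as.integer(roiSize), contrasts = contrasts,
              sliceNoiseSD = sliceNoiseSD,
              maskEllipticity = maskEllipticity,
              gradeFractionGII = gradeFractionGII,
              nullEffect = isTRUE(nullEffect), seed = as.integer(seed))
  class(cfg) <- "PhantomConfig"
  cfg
}

## reproducible per-(subject, contrast) seed fan-out, kept below 2^31
.subjectSeed <- function(masterSeed, subject, contrastIdx) {
  (as.numeric(masterSeed) * 7919 + subject * 613 +
     contrastIdx * 101) %% 2147483629 + 1
}

#' Generate one smoothed random texture field
#'
#' White Gaussian noise convolved with an isotropic Gaussian kernel of the
#' given correlation length (truncated at 3 standard deviations, computed on
#' a padded field so no wrap-around artifacts enter), then standardized to
#' mean 0 and standard deviation 1. A correlation length of 0 returns raw
#' white noise.
#'
#' @param roiSize integer c(height, width).
#' @param correlationLength Gaussian kernel standard deviation, in pixels
#'   (>= 0).
#' @param seed optional integer seed.
#' @return numeric matrix of dimension \code{roiSize}.
#' @export
generateTexture <- function(roiSize, correlationLength, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- roiSize[1L]; N <- roiSize[2L]
  if (correlationLength <= 0) {
    field <- matrix(stats::rnorm(M * N), M, N)
  } else {
    r <- max(1L, ceiling(3 * correlationLength))
    g <- stats::dnorm(seq(-r, r), sd = correlationLength)
    kernel <- outer(g, g); kernel <- kernel / sum(kernel)
    noise <- matrix(stats::rnorm((M + 2L * r) * (N + 2L * r)),
                    M + 2L * r, N + 2L * r)
    full <- .convFull2D(noise, kernel)
    field <- full[(2L * r + 1L):(2L * r + M),
                  (2L * r + 1L):(2L * r + N), drop = FALSE]
  }
  (field - mean(field)) / stats::sd(field)
}

## elliptical mask centered in an M x N image; axes jittered by `jitter`
.ellipseMask <- function(M, N, ellipticity, jitter = c(1, 1)) {
  a <- 0.40 * M * jitter[1L]              # row semi-axis
  b <- 0.40 * N * ellipticity * jitter[2L]
  cy <- (M + 1) / 2; cx <- (N + 1) / 2
  row <- matrix(seq_len(M), M, N)
  col <- matrix(seq_len(N), M, N, byrow = TRUE)
  1 * (((row - cy) / a)^2 + ((col - cx) / b)^2 <= 1)
}

#' Generate one raw phantom subject
#'
#' Produces the raw (pre-normalization) inputs for one subject and one
#' contrast: 3 slice images and 3 elliptical masks with small per-slice axis
#' jitter. Co-deleted-like subjects share one base texture plus independent
#' per-slice noise; non-deleted-like subjects get 3 independent textures.
#'
#' @param label \code{"co-deleted"} or \code{"non-deleted"}.
#' @param config a [phantomConfig()] object.
#' @param seed integer seed for this subject draw.
#' @param contrast contrast tag; must name an entry of
#'   \code{config$contrasts}.
#' @return list with elements \code{slices} (3 matrices), \code{masks}
#'   (3 binary matrices), \code{label}, \code{contrast}.
#' @export
generateSubject <- function(label, config, seed = NULL, contrast = NULL) {
  stopifnot(inherits(config, "PhantomConfig"))
  if (is.null(contrast)) contrast <- names(config$contrasts)[1L]
  if (!contrast %in% names(config$contrasts))
    stop("unknown contrast: ", contrast)
  if (!is.null(seed)) set.seed(seed)
  M <- config$roiSize[1L]; N <- config$roiSize[2L]
  cl <- config$contrasts[[contrast]]
  drawTexture <- function() generateTexture(c(M, N), cl)
  shared <- label == "co-deleted" && !config$nullEffect
  base <- drawTexture()
  ## per-slice jitter is texture of the same correlation length, so that as
  ## sliceNoiseSD grows the shared-texture class converges in distribution
  ## to independently drawn slices
  slices <- lapply(1:3, function(i) {
    if (shared) {
      if (config$sliceNoiseSD > 0)
        base + config$sliceNoiseSD * drawTexture()
      else base
    } else if (i == 1L) base else drawTexture()
  })
  masks <- lapply(1:3, function(i)
    .ellipseMask(M, N, config$maskEllipticity,
                 jitter = stats::runif(2L, 0.95, 1.05)))
  list(slices = slices, masks = masks, label = label, contrast = contrast)
}

## deterministic subject metadata table for a config
.cohortPlan <- function(config) {
  n <- config$nCodeleted + config$nNondeleted
  if (n == 0L) {
    return(data.frame(subject_id = character(0), label = character(0),
                      grade = character(0), stringsAsFactors = FALSE))
  }
  label <- c(rep("co-deleted", config$nCodeleted),
             rep("non-deleted", config$nNondeleted))
  grade <- unlist(lapply(c(config$nCodeleted, config$nNondeleted),
                         function(m) {
    if (m == 0L) return(character(0))
    nGII <- round(config$gradeFractionGII * m)
    c(rep("G-II", nGII), rep("G-III", m - nGII))
  }))
  data.frame(subject_id = sprintf("sub%03d", seq_len(n)), label = label,
             grade = grade, stringsAsFactors = FALSE)
}

#' Generate assembled phantom stacks in memory
#'
#' Draws the full cohort and runs each subject through the mask/crop/
#' normalize/pad workflow, returning ready-to-analyze stacks.
#'
#' @param config a [phantomConfig()] object.
#' @return list of [GliomaStack-class] objects (one per subject per
#'   contrast).
#' @export
phantomStacks <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  plan <- .cohortPlan(config)
  out <- list()
  for (i in seq_len(nrow(plan))) {
    for (j in seq_along(config$contrasts)) {
      ct <- names(config$contrasts)[j]
      subj <- generateSubject(plan$label[i], config,
                              seed = .subjectSeed(config$seed, i, j),
                              contrast = ct)
      out[[length(out) + 1L]] <- assembleStack(
        subj$slices, subj$masks, label = plan$label[i], contrast = ct,
        subjectID = plan$subject_id[i], grade = plan$grade[i])
    }
  }
  out
}

#' Generate a phantom cohort on disk
#'
#' Writes per-subject slice and mask PNGs plus a manifest CSV matching the
#' [readManifest()] contract. Slice intensities are min-max scaled to the
#' 8-bit PNG range per image (downstream z-scoring is shift/scale invariant,
#' so the method's input is unchanged up to 1/255 quantization); masks are
#' written as 0/255.
#'
#' @param config a [phantomConfig()] object.
#' @param dir output directory (created if needed).
#' @return path of the written manifest CSV, invisibly; the manifest
#'   data.frame is attached as attribute \code{manifest}.
#' @export
generateCohort <- function(config, dir) {
  stopifnot(inherits(config, "PhantomConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- .cohortPlan(config)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    sdir <- file.path(dir, plan$subject_id[i])
    dir.create(sdir, showWarnings = FALSE)
    for (j in seq_along(config$contrasts)) {
      ct <- names(config$contrasts)[j]
      subj <- generateSubject(plan$label[i], config,
                              seed = .subjectSeed(config$seed, i, j),
                              contrast = ct)
      sPaths <- mPaths <- character(3L)
      for (s in 1:3) {
        img <- subj$slices[[s]]
        rng <- range(img)
        img01 <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng)
                 else img * 0
        sPaths[s] <- file.path(plan$subject_id[i],
                               sprintf("%s_slice%d.png", ct, s))
        mPaths[s] <- file.path(plan$subject_id[i],
                               sprintf("%s_mask%d.png", ct, s))
        png::writePNG(img01, file.path(dir, sPaths[s]))
        png::writePNG(subj$masks[[s]], file.path(dir, mPaths[s]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = plan$subject_id[i], grade = plan$grade[i],
        contrast = ct, label = plan$label[i],
        slice1 = sPaths[1L], slice2 = sPaths[2L], slice3 = sPaths[3L],
        mask1 = mPaths[1L], mask2 = mPaths[2L], mask3 = mPaths[3L],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(matrix(character(0), 0L, 10L,
                dimnames = list(NULL, .manifestCols)))
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  attr(manifestPath, "manifest") <- manifest
  invisible(manifestPath)
}
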