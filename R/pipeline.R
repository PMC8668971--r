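#' Both consecutive-pair VoCC curves of a stack
#'
#' @param stack a [GliomaStack-class].
#' @param method correlation method, see [crossCorrelate2D()].
#' @return list with elements \code{pair12} and \code{pair23}
#'   ([VoCCCurve-class] objects).
#' @export
voccCurves <- function(stack, method = "fft") {
  s <- slices(stack)
  list(pair12 = voccPair(s[[1L]], s[[2L]], pairID = "pair12",
                         method = method),
       pair23 = voccPair(s[[2L]], s[[3L]], pairID = "pair23",
                         method = method))
}

#' Relative across-slice discrepancy of the VoCC pattern
#'
#' Quantifies how much the VoCC pattern changes between the two consecutive
#' slice pairs of a stack: ||V12 - V23||_2 / ||V12||_2 over the shared lag
#' axis. Stacks with consistent across-slice texture (co-deletion-like) give
#' small values; stacks whose texture is redrawn between slices give large
#' ones.
#'
#' @param stack a [GliomaStack-class].
#' @return non-negative scalar.
#' @export
voccDiscrepancy <- function(stack) {
  cv <- voccCurves(stack)
  v1 <- cv$pair12@variance; v2 <- cv$pair23@variance
  sqrt(sum((v1 - v2)^2)) / sqrt(sum(v1^2))
}

#' Spectral feature row for one subject stack
#'
#' Runs one stack through the spectral stage: VoCC curves for slice pairs
#' 1-2 and 2-3, Lomb-Scargle periodograms on a shared frequency grid,
#' first-peak exclusion, and the three classification features.
#'
#' @param stack a [GliomaStack-class].
#' @param oversample frequency grid oversampling factor
#'   (see [defaultFrequencyGrid()]).
#' @param epsilon cut-off threshold (see [cutoffFrequency()]).
#' @return one-row data.frame: subject_id, contrast, grade, label,
#'   difference_energy, total_volumetric_energy, cutoff_frequency.
#' @export
subjectSpectralFeatures <- function(stack, oversample = 4, epsilon = 0.01) {
  curves <- voccCurves(stack)
  grid <- defaultFrequencyGrid(length(curves$pair12@variance),
                               oversample = oversample)
  P12 <- lombScarglePSD(curves$pair12, grid)
  P23 <- lombScarglePSD(curves$pair23, grid)
  feats <- extractSpectralFeatures(P12, P23, epsilon = epsilon)
  cbind(data.frame(subject_id = subjectID(stack),
                   contrast = contrastTag(stack),
                   grade = tumorGrade(stack), label = stackLabel(stack),
                   stringsAsFactors = FALSE),
        feats)
}

#' Spectral feature table for a list of stacks
#'
#' Per-subject failures are caught, reported in a summary message, and the
#' affected rows skipped; if more than 20 percent of stacks fail the run is
#' aborted.
#'
#' @param stacks list of [GliomaStack-class] objects.
#' @param oversample,epsilon passed to [subjectSpectralFeatures()].
#' @return data.frame of feature rows with attribute \code{failures}
#'   (character vector of "subject/contrast: message").
#' @export
voccFeatures <- function(stacks, oversample = 4, epsilon = 0.01) {
  rows <- list(); failures <- character(0)
  for (stack in stacks) {
    r <- tryCatch(
      subjectSpectralFeatures(stack, oversample = oversample,
                              epsilon = epsilon),
      error = function(e) {
        failures <<- c(failures, paste0(subjectID(stack), "/",
                                        contrastTag(stack), ": ",
                                        conditionMessage(e)))
        NULL
      })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (length(failures) > 0.2 * length(stacks))
    stop("more than 20% of stacks failed feature extraction (",
         length(failures), "/", length(stacks), "); first failure: ",
         failures[1L])
  if (length(failures))
    message(length(failures), " stack(s) skipped during feature extraction")
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Pipeline configuration
#'
#' @param manifest path to a cohort manifest CSV (see [readManifest()]).
#' @param contrasts contrast tags to process; NULL (default) processes every
#'   contrast present in the manifest, each as an independent classification
#'   run.
#' @param oversample,epsilon spectral-stage parameters.
#' @param iterations,weakDepth RUSBoost parameters.
#' @param folds cross-validation folds k.
#' @param seed integer seed for undersampling and fold assignment.
#' @param outputDir optional directory for CSV outputs (features, VoCC
#'   curves, CV predictions); nothing is written when NULL.
#' @param combineContrasts if TRUE, one classification run on the
#'   concatenated per-contrast feature columns instead of per-contrast runs
#'   (off by default).
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(manifest, contrasts = NULL, oversample = 4,
                           epsilon = 0.01, iterations = 100L,
                           weakDepth = 2L, folds = 10L, seed = 1L,
                           outputDir = NULL, combineContrasts = FALSE) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  if (oversample <= 0 || epsilon <= 0 || epsilon >= 1)
    stop("oversample must be > 0 and epsilon in (0, 1)")
  if (iterations < 1L || folds < 2L) stop("need iterations >= 1, folds >= 2")
  cfg <- list(manifest = manifest, contrasts = contrasts,
              oversample = oversample, epsilon = epsilon,
              iterations = as.integer(iterations),
              weakDepth = as.integer(weakDepth), folds = as.integer(folds),
              seed = as.integer(seed), outputDir = outputDir,
              combineContrasts = isTRUE(combineContrasts))
  class(cfg) <- "PipelineConfig"
  cfg
}

.featureCols <- c("difference_energy", "total_volumetric_energy",
                  "cutoff_frequency")

#' Cross-validated classification of a spectral feature table
#'
#' Runs stratified k-fold RUSBoost cross-validation on the three spectral
#' features, independently for each imaging contrast (or once on
#' column-concatenated per-contrast features when
#' \code{combineContrasts = TRUE}).
#'
#' @param features feature table from [voccFeatures()].
#' @param folds,iterations,weakDepth,seed see [stratifiedKFoldCV()] and
#'   [trainRUSBoost()].
#' @param combineContrasts see [pipelineConfig()].
#' @return named list of \code{MetricsReport} objects, one per contrast (or
#'   one element \code{"combined"}).
#' @export
classifyFeatures <- function(features, folds = 10L, iterations = 100L,
                             weakDepth = 2L, seed = 1L,
                             combineContrasts = FALSE) {
  stopifnot(all(c(.featureCols, "label", "contrast") %in% names(features)))
  if (combineContrasts) {
    wide <- NULL
    for (ct in unique(features$contrast)) {
      sub <- features[features$contrast == ct,
                      c("subject_id", "label", .featureCols)]
      names(sub)[-(1:2)] <- paste(ct, .featureCols, sep = "_")
      wide <- if (is.null(wide)) sub
              else merge(wide, sub, by = c("subject_id", "label"))
    }
    x <- wide[, setdiff(names(wide), c("subject_id", "label")),
              drop = FALSE]
    return(list(combined = stratifiedKFoldCV(
      x, wide$label, k = folds, iterations = iterations,
      weakDepth = weakDepth, seed = seed)))
  }
  out <- list()
  for (ct in unique(features$contrast)) {
    sub <- features[features$contrast == ct, , drop = FALSE]
    out[[ct]] <- stratifiedKFoldCV(sub[, .featureCols], sub$label,
                                   k = folds, iterations = iterations,
                                   weakDepth = weakDepth, seed = seed)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Manifest -> assembled stacks -> VoCC curves -> Lomb-Scargle periodograms
#' -> spectral features -> stratified k-fold RUSBoost cross-validation, with
#' per-stage progress messages. Deterministic for a fixed config seed.
#'
#' @param config a [pipelineConfig()] object.
#' @return list with elements \code{features} (data.frame), \code{metrics}
#'   (named list of \code{MetricsReport} per contrast), \code{failures}
#'   (skipped stacks) and \code{config}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[%7.2fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))
  man <- readManifest(config$manifest)
  if (!is.null(config$contrasts))
    man <- man[man$contrast %in% config$contrasts, , drop = FALSE]
  if (!nrow(man)) stop("manifest has no rows for the requested contrasts")
  stage(paste("manifest:", nrow(man), "stack(s),",
              length(unique(man$subject_id)), "subject(s)"))
  baseDir <- attr(man, "baseDir")
  stacks <- list(); readFail <- character(0)
  for (i in seq_len(nrow(man))) {
    st <- tryCatch(readSubjectStack(man[i, ], baseDir = baseDir),
                   error = function(e) {
                     readFail <<- c(readFail,
                                    paste0(man$subject_id[i], "/",
                                           man$contrast[i], ": ",
                                           conditionMessage(e)))
                     NULL
                   })
    if (!is.null(st)) stacks[[length(stacks) + 1L]] <- st
  }
  if (length(readFail) > 0.2 * nrow(man))
    stop("more than 20% of stacks failed to load; first failure: ",
         readFail[1L])
  stage(paste("stacks assembled:", length(stacks)))
  features <- voccFeatures(stacks, oversample = config$oversample,
                           epsilon = config$epsilon)
  stage(paste("features extracted:", nrow(features), "row(s)"))
  metrics <- classifyFeatures(features, folds = config$folds,
                              iterations = config$iterations,
                              weakDepth = config$weakDepth,
                              seed = config$seed,
                              combineContrasts = config$combineContrasts)
  stage("cross-validation complete")
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    hdr <- sprintf("# seed=%d oversample=%g epsilon=%g iterations=%d folds=%d",
                   config$seed, config$oversample, config$epsilon,
                   config$iterations, config$folds)
    writeTbl <- function(df, name) {
      path <- file.path(config$outputDir, name)
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(df, path, append = TRUE,
                                          sep = ",", row.names = FALSE,
                                          qmethod = "double"))
    }
    writeTbl(features, "features.csv")
    curves <- do.call(rbind, lapply(stacks, function(st) {
      cv <- voccCurves(st)
      rbind(as.data.frame(cv$pair12, subject_id = subjectID(st),
                          contrast = contrastTag(st)),
            as.data.frame(cv$pair23, subject_id = subjectID(st),
                          contrast = contrastTag(st)))
    }))
    writeTbl(curves, "vocc_curves.csv")
    preds <- do.call(rbind, lapply(names(metrics), function(ct)
      cbind(contrast = ct, metrics[[ct]]$predictions)))
    writeTbl(preds, "cv_predictions.csv")
    stage(paste("outputs written to", config$outputDir))
  }
  list(features = features, metrics = metrics,
       failures = c(readFail, attr(features, "failures")),
       config = config)
}
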