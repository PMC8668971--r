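#' @rdname GliomaStack-accessors
#' @export
setMethod("slices", "GliomaStack", function(x) x@slices)

#' @rdname GliomaStack-accessors
#' @export
setMethod("stackLabel", "GliomaStack", function(x) x@label)

#' @rdname GliomaStack-accessors
#' @export
setMethod("contrastTag", "GliomaStack", function(x) x@contrast)

#' @rdname GliomaStack-accessors
#' @export
setMethod("subjectID", "GliomaStack", function(x) x@subjectID)

#' @rdname GliomaStack-accessors
#' @export
setMethod("tumorGrade", "GliomaStack", function(x) x@grade)

#' @rdname VoCCCurve-accessors
#' @export
setMethod("lags", "VoCCCurve", function(x) x@lags)

#' @rdname VoCCCurve-accessors
#' @export
setMethod("curveVariance", "VoCCCurve", function(x) x@variance)

#' @rdname VoCCCurve-accessors
#' @export
setMethod("pairID", "VoCCCurve", function(x) x@pairID)

#' @rdname PowerSpectrum-accessors
#' @export
setMethod("frequencies", "PowerSpectrum", function(x) x@frequencies)

#' @rdname PowerSpectrum-accessors
#' @export
setMethod("spectralPower", "PowerSpectrum", function(x) x@power)

#' @rdname RUSBoostModel-accessors
#' @export
setMethod("voteWeights", "RUSBoostModel", function(x) x@voteWeights)

#' @rdname RUSBoostModel-accessors
#' @export
setMethod("weakHypotheses", "RUSBoostModel", function(x) x@hypotheses)

setMethod("show", "GliomaStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat("GliomaStack for subject", object@subjectID, "\n")
  cat("  slices   : 3 x [", d[1L], "x", d[2L], "] (masked, z-normalized)\n")
  cat("  label    :", object@label, "  grade:", object@grade,
      "  contrast:", object@contrast, "\n")
})

setMethod("show", "VoCCCurve", function(object) {
  cat("VoCCCurve (", object@pairID, "), ", length(object@lags),
      " column lags [", min(object@lags), "..", max(object@lags), "]\n",
      sep = "")
  cat("  variance range: [", format(min(object@variance), digits = 4), ", ",
      format(max(object@variance), digits = 4), "]\n", sep = "")
})

setMethod("show", "PowerSpectrum", function(object) {
  cat("PowerSpectrum with ", length(object@frequencies), " frequencies in [",
      format(min(object@frequencies), digits = 4), ", ",
      format(max(object@frequencies), digits = 4), "] cycles/lag\n", sep = "")
  if (length(object@power))
    cat("  peak power ", format(max(object@power), digits = 4), " at f = ",
        format(object@frequencies[which.max(object@power)], digits = 4),
        "\n", sep = "")
})

setMethod("show", "RUSBoostModel", function(object) {
  cat("RUSBoostModel:", length(object@hypotheses), "weak hypotheses\n")
  cat("  classes  :", paste(object@classes, collapse = " vs "),
      " (minority:", object@minorityClass, ")\n")
  cat("  weak learner:",
      paste(names(object@weakLearnerSpec),
            unlist(lapply(object@weakLearnerSpec, format)),
            sep = "=", collapse = ", "), "\n")
})

#' Convert a VoCCCurve to a data.frame
#'
#' @param x a [VoCCCurve-class] object.
#' @param row.names,optional ignored, present for generic compatibility.
#' @param ... further attributes (e.g. \code{subject_id}, \code{contrast})
#'   recycled into extra columns.
#' @return data.frame with columns \code{lag}, \code{variance},
#'   \code{pair_id}, plus any columns supplied via \code{...}.
#' @export
as.data.frame.VoCCCurve <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  out <- data.frame(lag = x@lags, variance = x@variance, pair_id = x@pairID,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Convert a PowerSpectrum to a data.frame
#'
#' @param x a [PowerSpectrum-class] object.
#' @param row.names,optional ignored, present for generic compatibility.
#' @param ... extra columns, recycled.
#' @return data.frame with columns \code{frequency}, \code{power}.
#' @export
as.data.frame.PowerSpectrum <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  out <- data.frame(frequency = x@frequencies, power = x@power)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}
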