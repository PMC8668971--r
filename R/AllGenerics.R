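#' @describeIn GliomaStack-accessors list of the 3 slice matrices
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @describeIn GliomaStack-accessors co-deletion status label
#' @export
setGeneric("stackLabel", function(x) standardGeneric("stackLabel"))

#' @describeIn GliomaStack-accessors imaging contrast tag
#' @export
setGeneric("contrastTag", function(x) standardGeneric("contrastTag"))

#' @describeIn GliomaStack-accessors subject identifier
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @describeIn GliomaStack-accessors tumor grade
#' @export
setGeneric("tumorGrade", function(x) standardGeneric("tumorGrade"))

#' @describeIn VoCCCurve-accessors integer column lags
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' @describeIn VoCCCurve-accessors per-lag variance values
#' @export
setGeneric("curveVariance", function(x) standardGeneric("curveVariance"))

#' @describeIn VoCCCurve-accessors slice-pair identifier
#' @export
setGeneric("pairID", function(x) standardGeneric("pairID"))

#' @describeIn PowerSpectrum-accessors frequency grid (cycles per lag)
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @describeIn PowerSpectrum-accessors spectral power values
#' @export
setGeneric("spectralPower", function(x) standardGeneric("spectralPower"))

#' @describeIn RUSBoostModel-accessors ensemble vote weights log(1/a_t)
#' @export
setGeneric("voteWeights", function(x) standardGeneric("voteWeights"))

#' @describeIn RUSBoostModel-accessors list of fitted weak hypotheses
#' @export
setGeneric("weakHypotheses", function(x) standardGeneric("weakHypotheses"))

#' Accessors for GliomaStack objects
#'
#' @param x a [GliomaStack-class] object.
#' @name GliomaStack-accessors
#' @aliases slices stackLabel contrastTag subjectID tumorGrade
NULL

#' Accessors for VoCCCurve objects
#'
#' @param x a [VoCCCurve-class] object.
#' @name VoCCCurve-accessors
#' @aliases lags curveVariance pairID
NULL

#' Accessors for PowerSpectrum objects
#'
#' @param x a [PowerSpectrum-class] object.
#' @name PowerSpectrum-accessors
#' @aliases frequencies spectralPower
NULL

#' Accessors for RUSBoostModel objects
#'
#' @param x a [RUSBoostModel-class] object.
#' @name RUSBoostModel-accessors
#' @aliases voteWeights weakHypotheses
NULL
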