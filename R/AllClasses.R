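#' @import methods
NULL

#' GliomaStack: three masked, normalized tumor ROI slices from one subject
#'
#' Container for one subject's stack of 3 consecutive cropped, masked and
#' z-score-normalized region-of-interest slices for a single imaging contrast,
#' together with the subject's class label and metadata. All three slices share
#' one common height and width (centered zero-padding to the largest per-slice
#' bounding box), and pixels outside the tumor mask are exactly 0.
#'
#' @slot slices list of exactly 3 numeric matrices of identical dimensions.
#' @slot label character, \code{"co-deleted"} or \code{"non-deleted"}
#'   (1p/19q co-deletion status).
#' @slot contrast character, imaging contrast tag (\code{"T1C"} or \code{"T2W"}).
#' @slot subjectID character identifier.
#' @slot grade character, tumor grade (\code{"G-II"} or \code{"G-III"}).
#'
#' @seealso [assembleStack()] which constructs validated objects.
#' @export
setClass("GliomaStack",
  representation(
    slices = "list",
    label = "character",
    contrast = "character",
    subjectID = "character",
    grade = "character"
  )
)

.validGliomaStack <- function(object) {
  msg <- NULL
  s <- object@slices
  if (length(s) != 3L)
    msg <- c(msg, "a GliomaStack must contain exactly 3 slices")
  if (!all(vapply(s, is.matrix, logical(1L))))
    msg <- c(msg, "all slices must be numeric matrices")
  if (length(s) == 3L && all(vapply(s, is.matrix, logical(1L)))) {
    dims <- vapply(s, dim, integer(2L))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
      msg <- c(msg, "all 3 slices must share one common height and width")
    if (!all(vapply(s, function(m) all(is.finite(m)), logical(1L))))
      msg <- c(msg, "slice pixels must all be finite")
  }
  if (!object@label %in% c("co-deleted", "non-deleted"))
    msg <- c(msg, "label must be 'co-deleted' or 'non-deleted'")
  if (length(object@contrast) != 1L || !nzchar(object@contrast))
    msg <- c(msg, "contrast must be a single non-empty string")
  if (is.null(msg)) TRUE else msg
}
setValidity("GliomaStack", .validGliomaStack)

#' VoCCCurve: variance of cross-correlation as a function of lag
#'
#' The variance-of-cross-correlation (VoCC) statistic for one pair of
#' consecutive slices: for each column (horizontal) lag j of the full 2D
#' cross-correlation, the sample variance of the correlation values over the
#' row (vertical) lags. The lag axis has length 2N-1 for N-column inputs.
#'
#' @slot lags integer vector of column lags, -(N-1)..(N-1).
#' @slot variance non-negative numeric vector, same length as \code{lags}.
#' @slot pairID character, which slice pair the curve belongs to
#'   (\code{"pair12"} or \code{"pair23"}).
#'
#' @seealso [vocc()], [voccPair()]
#' @export
setClass("VoCCCurve",
  representation(
    lags = "integer",
    variance = "numeric",
    pairID = "character"
  )
)

setValidity("VoCCCurve", function(object) {
  msg <- NULL
  if (length(object@lags) != length(object@variance))
    msg <- c(msg, "lags and variance must have equal length")
  if (any(!is.finite(object@variance)))
    msg <- c(msg, "variance values must be finite")
  if (any(object@variance < -1e-12))
    msg <- c(msg, "variance values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' PowerSpectrum: frequency grid with spectral power values
#'
#' A one-sided power spectrum on a strictly increasing grid of positive
#' frequencies (cycles per lag unit), as produced by the Lomb-Scargle
#' periodogram of a VoCC curve, or by the elementwise (inner) product of two
#' such periodograms.
#'
#' @slot frequencies strictly increasing positive numeric vector.
#' @slot power non-negative numeric vector, same length.
#'
#' @seealso [lombScarglePSD()], [innerProductSpectrum()]
#' @export
setClass("PowerSpectrum",
  representation(
    frequencies = "numeric",
    power = "numeric"
  )
)

setValidity("PowerSpectrum", function(object) {
  msg <- NULL
  f <- object@frequencies
  if (length(f) != length(object@power))
    msg <- c(msg, "frequencies and power must have equal length")
  if (length(f) && (any(f <= 0) || any(diff(f) <= 0)))
    msg <- c(msg, "frequencies must be positive and strictly increasing")
  if (any(!is.finite(object@power)) || any(object@power < -1e-12))
    msg <- c(msg, "power must be finite and non-negative")
  if (is.null(msg)) TRUE else msg
})

#' RUSBoostModel: trained random-undersampling boosting ensemble
#'
#' A boosted ensemble of weak hypotheses, each trained on a class-balanced
#' (1:1) random undersample of the weighted training set, with vote weights
#' log(1/a_t) derived from the AdaBoost.M2 pseudo-loss on the full set.
#'
#' @slot hypotheses list of fitted weak hypotheses (rpart trees).
#' @slot voteWeights numeric vector of ensemble vote weights, one per
#'   hypothesis.
#' @slot classes character vector of the two class levels (training order).
#' @slot minorityClass character, the minority class label at training time;
#'   ties in the weighted vote break toward it.
#' @slot weakLearnerSpec list describing the base learner configuration.
#' @slot history data.frame with one row per accepted boosting iteration:
#'   pseudo-loss, vote weight, post-update weight sum and minimum, and the
#'   class composition of the undersampled training set.
#'
#' @seealso [trainRUSBoost()], [predict,RUSBoostModel-method]
#' @export
setClass("RUSBoostModel",
  representation(
    hypotheses = "list",
    voteWeights = "numeric",
    classes = "character",
    minorityClass = "character",
    weakLearnerSpec = "list",
    history = "data.frame"
  )
)

setValidity("RUSBoostModel", function(object) {
  msg <- NULL
  if (length(object@hypotheses) < 1L)
    msg <- c(msg, "an ensemble needs at least one weak hypothesis")
  if (length(object@voteWeights) != length(object@hypotheses))
    msg <- c(msg, "one vote weight per hypothesis is required")
  if (any(!is.finite(object@voteWeights)))
    msg <- c(msg, "vote weights must be finite")
  if (length(object@classes) != 2L)
    msg <- c(msg, "exactly two classes are supported")
  if (is.null(msg)) TRUE else msg
})
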