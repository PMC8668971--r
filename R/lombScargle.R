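#' Default frequency grid for periodogram estimation
#'
#' Builds an arithmetic grid from 1/(oversample * T) to the Nyquist limit of
#' 0.5 cycles per lag (unit lag spacing) in steps of 1/(oversample * T),
#' where T is the span of the lag axis (n_samples - 1 for unit spacing).
#'
#' @param nSamples number of samples of the curve (>= 4).
#' @param oversample oversampling factor (> 0); larger gives a denser grid.
#' @return numeric vector of frequencies (cycles per lag).
#' @examples
#' head(defaultFrequencyGrid(101, oversample = 1))  # 0.01, 0.02, ...
#' @export
defaultFrequencyGrid <- function(nSamples, oversample = 4) {
  if (nSamples < 4L) stop("need at least 4 samples for a frequency grid")
  if (oversample <= 0) stop("oversample must be positive")
  Tspan <- nSamples - 1
  df <- 1 / (oversample * Tspan)
  seq(df, 0.5, by = df)
}

#' Lomb-Scargle power spectral density of a VoCC curve
#'
#' Classical Lomb-Scargle periodogram of the (mean-centered) curve, with the
#' per-frequency phase offset tau that makes the cosine and sine components
#' orthogonal and the estimate invariant to time shifts:
#' \deqn{P(f) = \frac{1}{2}\left[
#'   \frac{(\sum_n x_n \cos\omega(t_n-\tau))^2}{\sum_n \cos^2\omega(t_n-\tau)}
#' + \frac{(\sum_n x_n \sin\omega(t_n-\tau))^2}{\sum_n \sin^2\omega(t_n-\tau)}
#' \right],}
#' with \eqn{\omega = 2\pi f} and
#' \eqn{\tan(2\omega\tau) = \sum_n \sin 2\omega t_n / \sum_n \cos 2\omega t_n}.
#' Sampling positions are the integer lag indices 1..length(curve). Because
#' the lag axis is uniformly sampled this coincides with the classical
#' periodogram; the Lomb-Scargle form is kept so unevenly spaced lag axes are
#' handled identically.
#'
#' With \code{normalization = "standard"} (the default) the power is divided
#' by the sample variance of the centered curve, Scargle's significance
#' normalization. VoCC curves from different subjects differ by orders of
#' magnitude in scale (the coherent correlation peak grows with ROI size and
#' across-slice similarity), so spectra entering cross-subject features must
#' be scale-free; the normalized periodogram measures how the curve's
#' variance distributes over frequency. \code{"psd"} gives the raw
#' least-squares power (half the fitted sum of squares of the best sinusoid
#' at each frequency).
#'
#' @param curve a [VoCCCurve-class] or a plain numeric vector.
#' @param frequencies positive, strictly increasing frequencies (cycles per
#'   lag); defaults to [defaultFrequencyGrid()] for the curve length.
#' @param center mean-center the curve first (default TRUE; the DC component
#'   otherwise swamps the spectrum).
#' @param normalization \code{"standard"} (power relative to the curve's
#'   sample variance) or \code{"psd"} (raw power).
#' @return a [PowerSpectrum-class].
#' @export
lombScarglePSD <- function(curve, frequencies = NULL, center = TRUE,
                           normalization = c("standard", "psd")) {
  normalization <- match.arg(normalization)
  x <- if (is(curve, "VoCCCurve")) curve@variance else as.numeric(curve)
  if (length(x) < 4L) stop("curve must have at least 4 samples")
  if (any(!is.finite(x))) stop("curve contains non-finite values")
  if (is.null(frequencies)) frequencies <- defaultFrequencyGrid(length(x))
  f <- as.numeric(frequencies)
  if (any(f <= 0) || any(diff(f) <= 0))
    stop("frequencies must be positive and strictly increasing")
  if (center) x <- x - mean(x)
  tn <- seq_along(x)
  omega <- 2 * pi * f
  ## tau per frequency: atan2(sum sin(2 w t), sum cos(2 w t)) / (2 w)
  wt2 <- outer(tn, 2 * omega)              # n x F
  tau <- atan2(colSums(sin(wt2)), colSums(cos(wt2))) / (2 * omega)
  arg <- outer(tn, omega) - rep(omega * tau, each = length(tn))
  ct <- cos(arg); st <- sin(arg)
  numC <- colSums(x * ct)^2
  numS <- colSums(x * st)^2
  denC <- colSums(ct^2)
  denS <- colSums(st^2)
  eps <- 1e-12 * length(x)
  pc <- ifelse(denC > eps, numC / denC, 0)
  ps <- ifelse(denS > eps, numS / denS, 0)
  p <- 0.5 * (pc + ps)
  if (normalization == "standard") {
    v <- stats::var(x)
    p <- if (v > 0) p / v else rep(0, length(p))  # constant curve: no power
  }
  p[p < 0] <- 0  # guard tiny negative round-off
  new("PowerSpectrum", frequencies = f, power = p)
}

#' Inner product of two periodograms
#'
#' Elementwise product of the power values of two spectra on an identical
#' frequency grid. Peaks that persist in both input spectra (static
#' volumetric periodicity) survive the product; peaks present in only one
#' are suppressed.
#'
#' @param P12,P23 [PowerSpectrum-class] objects on the same grid.
#' @return a [PowerSpectrum-class].
#' @export
innerProductSpectrum <- function(P12, P23) {
  stopifnot(is(P12, "PowerSpectrum"), is(P23, "PowerSpectrum"))
  if (length(P12@frequencies) != length(P23@frequencies) ||
      any(abs(P12@frequencies - P23@frequencies) > 1e-12))
    stop("frequency grids differ; spectra must share one grid")
  new("PowerSpectrum", frequencies = P12@frequencies,
      power = P12@power * P23@power)
}

## number of leading grid points to drop under the first-peak exclusion rule:
## everything up to and including the first interior local minimum that
## follows the first local maximum; if no interior local minimum exists, the
## leading strictly-decreasing run.
.firstPeakCut <- function(p) {
  n <- length(p)
  if (n < 5L) stop("need at least 5 spectral points for first-peak exclusion")
  isMax <- function(i) (i == 1L || p[i] > p[i - 1L]) &&
    (i == n || p[i] >= p[i + 1L])
  m <- 0L
  for (i in seq_len(n - 1L)) if (isMax(i)) { m <- i; break }
  if (m > 0L) {
    for (j in (m + 1L):(n - 1L)) {
      if (p[j] <= p[j - 1L] && p[j] < p[j + 1L]) return(j)
    }
  }
  ## no interior local minimum: drop the leading strictly-decreasing run
  j <- 1L
  while (j < n && p[j + 1L] < p[j]) j <- j + 1L
  j
}

#' Exclude the low-frequency first peak of a spectrum
#'
#' Imaging spectra carry a dominant low-frequency component that appears in
#' both classes and carries no discriminative information, so the band up to
#' and including the first interior local minimum following the first local
#' maximum of power is removed. If the power has no interior local minimum,
#' the leading strictly-decreasing run is removed instead.
#'
#' @param spec a [PowerSpectrum-class] with at least 5 points.
#' @return the truncated [PowerSpectrum-class].
#' @examples
#' s <- new("PowerSpectrum", frequencies = (1:5) / 10,
#'          power = c(9, 4, 1, 6, 3))
#' spectralPower(excludeFirstPeak(s))  # 6 3
#' @export
excludeFirstPeak <- function(spec) {
  stopifnot(is(spec, "PowerSpectrum"))
  cut <- .firstPeakCut(spec@power)
  if (length(spec@power) - cut < 2L)
    stop("spectrum exhausted: fewer than 2 points remain after exclusion")
  keep <- (cut + 1L):length(spec@power)
  new("PowerSpectrum", frequencies = spec@frequencies[keep],
      power = spec@power[keep])
}

#' Cut-off frequency of a spectrum
#'
#' The smallest grid frequency f* at which the power is below
#' \code{epsilon * max(power)} and stays below it at every larger frequency
#' ("the frequency at which the spectrum is nearly zero"). If the power never
#' stays below the threshold, the largest grid frequency is returned.
#'
#' @param spec a non-empty [PowerSpectrum-class] with positive maximum power.
#' @param epsilon relative threshold in (0, 1); default 0.01.
#' @return a single frequency (cycles per lag).
#' @export
cutoffFrequency <- function(spec, epsilon = 0.01) {
  stopifnot(is(spec, "PowerSpectrum"))
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  p <- spec@power
  if (!length(p) || max(p) <= 0)
    stop("cutoff frequency undefined for an all-zero spectrum")
  thr <- epsilon * max(p)
  ## running maximum of the suffix p[k..end]
  sufMax <- rev(cummax(rev(p)))
  k <- which(sufMax < thr)
  if (length(k)) spec@frequencies[k[1L]] else max(spec@frequencies)
}

#' Extract the three spectral classification features
#'
#' From the periodograms of the two slice-pair VoCC curves, computes
#' (i) the difference energy |sum P12 - sum P23|, (ii) the total volumetric
#' energy sum(P12 * P23) of the inner-product spectrum, and (iii) the cut-off
#' frequency of the inner-product spectrum. With
#' \code{excludeFirst = TRUE} (the default) the first-peak exclusion band is
#' determined on the inner-product spectrum and the same band is removed from
#' both periodograms, so all three features refer to one retained band.
#'
#' @param P12,P23 [PowerSpectrum-class] objects on a shared grid
#'   (slice pair 1-2 and 2-3).
#' @param epsilon threshold for [cutoffFrequency()].
#' @param excludeFirst apply first-peak exclusion (default TRUE).
#' @return one-row data.frame with columns \code{difference_energy},
#'   \code{total_volumetric_energy}, \code{cutoff_frequency}.
#' @export
extractSpectralFeatures <- function(P12, P23, epsilon = 0.01,
                                    excludeFirst = TRUE) {
  inner <- innerProductSpectrum(P12, P23)
  if (excludeFirst) {
    cut <- .firstPeakCut(inner@power)
    if (length(inner@power) - cut < 2L)
      stop("spectrum exhausted: fewer than 2 points remain after exclusion")
    keep <- (cut + 1L):length(inner@power)
    P12 <- new("PowerSpectrum", frequencies = P12@frequencies[keep],
               power = P12@power[keep])
    P23 <- new("PowerSpectrum", frequencies = P23@frequencies[keep],
               power = P23@power[keep])
    inner <- new("PowerSpectrum", frequencies = inner@frequencies[keep],
                 power = inner@power[keep])
  }
  data.frame(
    difference_energy = abs(sum(P12@power) - sum(P23@power)),
    total_volumetric_energy = sum(inner@power),
    cutoff_frequency = cutoffFrequency(inner, epsilon = epsilon)
  )
}
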