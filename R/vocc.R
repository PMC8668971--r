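## full 2D linear convolution via FFT; A (a1 x a2), B (b1 x b2)
.convFull2D <- function(A, B) {
  M <- nrow(A) + nrow(B) - 1L
  N <- ncol(A) + ncol(B) - 1L
  Ap <- matrix(0, M, N); Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  Bp <- matrix(0, M, N); Bp[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  Re(stats::fft(stats::fft(Ap) * stats::fft(Bp), inverse = TRUE)) / (M * N)
}

#' Full-lag 2D cross-correlation of two equal-size slices
#'
#' Computes C(i, j) = sum_{m,n} X(m, n) Y(m - i, n - j) for all vertical lags
#' i in -(M-1)..(M-1) and horizontal lags j in -(N-1)..(N-1), with
#' out-of-range Y terms treated as zero ("full" correlation). The result is a
#' (2M-1) x (2N-1) matrix whose row r corresponds to lag i = r - M and column
#' c to lag j = c - N.
#'
#' @param X,Y numeric matrices of identical dimensions M x N.
#' @param method \code{"fft"} (default; zero-padded FFT convolution with the
#'   axis-reversed second image) or \code{"direct"} (literal double sum,
#'   intended for small inputs and verification).
#' @return numeric matrix of dimension (2M-1) x (2N-1) with attributes
#'   \code{rowLags} and \code{colLags}.
#' @examples
#' crossCorrelate2D(matrix(1, 2, 2), matrix(1, 2, 2))
#' @export
crossCorrelate2D <- function(X, Y, method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(is.matrix(X), is.matrix(Y))
  if (!identical(dim(X), dim(Y)))
    stop("X and Y must have identical dimensions")
  M <- nrow(X); N <- ncol(X)
  if (method == "fft") {
    C <- .convFull2D(X, Y[M:1, N:1, drop = FALSE])
  } else {
    C <- matrix(0, 2L * M - 1L, 2L * N - 1L)
    for (i in (-(M - 1L)):(M - 1L)) {
      for (j in (-(N - 1L)):(N - 1L)) {
        m <- seq_len(M); n <- seq_len(N)
        mOK <- m[m - i >= 1L & m - i <= M]
        nOK <- n[n - j >= 1L & n - j <= N]
        if (length(mOK) && length(nOK))
          C[i + M, j + N] <- sum(X[mOK, nOK, drop = FALSE] *
                                   Y[mOK - i, nOK - j, drop = FALSE])
      }
    }
  }
  attr(C, "rowLags") <- (-(M - 1L)):(M - 1L)
  attr(C, "colLags") <- (-(N - 1L)):(N - 1L)
  C
}

#' Variance of cross-correlation (VoCC) over lags
#'
#' For each column (horizontal) lag j of a full cross-correlation matrix,
#' computes the sample variance of C(., j) over the row (vertical) lags:
#' sum_i (C(i,j) - mean_i C(i,j))^2 / (rows - 1). For a (2M-1)-row matrix the
#' denominator is 2M-2.
#'
#' @param C cross-correlation matrix from [crossCorrelate2D()].
#' @param pairID slice-pair tag stored on the curve (\code{"pair12"} or
#'   \code{"pair23"}).
#' @param margin \code{"column"} (default: variance over row lags, indexed by
#'   column lag) or \code{"row"} (the transposed variant).
#' @return a [VoCCCurve-class].
#' @export
vocc <- function(C, pairID = "pair12", margin = c("column", "row")) {
  margin <- match.arg(margin)
  stopifnot(is.matrix(C))
  if (margin == "row") {
    lagAttr <- attr(C, "rowLags")
    C <- t(C)
  } else {
    lagAttr <- attr(C, "colLags")
  }
  if (nrow(C) < 2L)
    stop("variance over row lags needs at least 2 rows (denominator 2M-2)")
  v <- apply(C, 2L, stats::var)
  lagVals <- if (!is.null(lagAttr)) as.integer(lagAttr)
             else as.integer(seq_len(ncol(C)) - (ncol(C) + 1L) %/% 2L)
  new("VoCCCurve", lags = lagVals, variance = as.numeric(v), pairID = pairID)
}

#' VoCC curve for a pair of consecutive slices
#'
#' Convenience composition of [crossCorrelate2D()] and [vocc()].
#'
#' @param X,Y numeric matrices of identical dimensions (two consecutive
#'   masked, normalized slices).
#' @param pairID slice-pair tag.
#' @param method correlation method, see [crossCorrelate2D()].
#' @return a [VoCCCurve-class].
#' @export
voccPair <- function(X, Y, pairID = "pair12", method = "fft") {
  vocc(crossCorrelate2D(X, Y, method = method), pairID = pairID)
}
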