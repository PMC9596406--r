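# Periodogram-based spectral scaling.

#' Raw periodogram of a series
#'
#' S(f) = |sum_j x_j exp(-2 pi i f j / N)|^2 at integer frequency indices f
#' (cycles per record). No taper and no segment averaging: variance of the
#' raw estimator is reduced by averaging curves across sessions
#' (\code{\link{averageCurves}}), not by smoothing. By default only
#' 1 <= f <= floor(N/2) is retained (f = 0 carries the mean and is excluded
#' from scaling fits); with `retain = FALSE` all N bins f = 0..N-1 are
#' returned, which satisfy Parseval's identity
#' sum_f S(f) = N * sum_j x_j^2.
#'
#' @param series numeric vector, length >= 8.
#' @param retain keep only the fit band 1..floor(N/2)? (default TRUE)
#' @return A \linkS4class{SpectrumCurve}; when `retain = FALSE`, a plain
#'   numeric vector of all N periodogram values (bin f = 0 first).
#' @examples
#' psdBeta(generatePowerLawSignal(1, 1024, seed = 3))
#' @export
psdCurve <- function(series, retain = TRUE) {
  N <- length(series)
  if (N < 8L) stop("'series' must have length >= 8", call. = FALSE)
  S <- Mod(fft(series))^2
  if (!retain) return(S)
  half <- N %/% 2L
  new("SpectrumCurve", scales = as.numeric(seq_len(half)),
      values = S[1L + seq_len(half)])
}

#' Default periodogram fit band
#'
#' Frequency indices 2..floor(N/8): the lowest bin is dropped to avoid DC
#' leakage and the upper half-decade to avoid the high-frequency noise
#' floor.
#'
#' @param n series length.
#' @return numeric length-2 fit range of frequency indices.
#' @export
psdFitRange <- function(n) c(2, floor(n / 8))

#' Estimate the spectral exponent beta of a series
#'
#' Fits S(f) ~ 1/f^beta on the raw periodogram over `fitRange`
#' (default \code{\link{psdFitRange}}).
#'
#' @inheritParams psdCurve
#' @param fitRange frequency-index range for the log-log fit.
#' @return A \linkS4class{ScalingFit} of kind "spectral".
#' @export
psdBeta <- function(series, fitRange = psdFitRange(length(series))) {
  fitScaling(psdCurve(series), fitRange)
}

#' Convert between the Hurst and spectral exponents
#'
#' For fractal signals the periodogram decay and the DFA scaling are two
#' views of the same long-range correlation: beta = 2H - 1.
#'
#' @param h Hurst exponent.
#' @param beta spectral exponent.
#' @return the corresponding other exponent.
#' @examples
#' betaFromHurst(1.2)  # 1.4
#' hurstFromBeta(0)    # 0.5
#' @export
betaFromHurst <- function(h) {
  stopifnot(is.finite(h))
  2 * h - 1
}

#' @rdname betaFromHurst
#' @export
hurstFromBeta <- function(beta) {
  stopifnot(is.finite(beta))
  (beta + 1) / 2
}
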