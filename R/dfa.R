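# Detrended fluctuation analysis.

#' Cumulative profile of a series
#'
#' The mean-centred cumulative sum X(j) = sum_{i<=j} (x_i - <x>). Its last
#' element is zero up to floating-point rounding (telescoping).
#'
#' @param series numeric vector, length >= 2.
#' @return numeric vector of the same length.
#' @examples
#' dfaProfile(c(1, 2, 3))  # -1 -1 0
#' @export
dfaProfile <- function(series) {
  if (length(series) < 2L || any(!is.finite(series)))
    stop("'series' must be finite with length >= 2", call. = FALSE)
  cumsum(series - mean(series))
}

# Residuals of order-m polynomial detrending over both-ends segmentation of
# a profile: columns are segments nu = 1..2*Ns (forward 1..Ns anchored at
# the start, backward Ns+1..2*Ns anchored at the end, per the end-anchored
# indexing X(N - (nu - Ns) s + k)). The polynomial is fit on within-segment
# index k = 1..s.
segmentResiduals <- function(X, s, m) {
  N <- length(X)
  Ns <- N %/% s
  V <- outer(seq_len(s), 0:m, "^")
  Q <- qr.Q(qr(V))
  fwd <- matrix(X[seq_len(Ns * s)], nrow = s)
  bwdIdx <- as.vector(vapply(seq_len(Ns), function(j)
    N - j * s + seq_len(s), integer(s)))
  bwd <- matrix(X[bwdIdx], nrow = s)
  seg <- cbind(fwd, bwd)
  seg - Q %*% crossprod(Q, seg)
}

#' Default logarithmic DFA scale grid
#'
#' About 20 log-spaced integer scales in [6, N/4]: the upper bound keeps at
#' least 8 segments (4 per direction) at the largest scale, the lower bound
#' exceeds the quadratic-detrending support m + 1.
#'
#' @param n series length.
#' @param sMin,sMax scale bounds in frames.
#' @param nScales approximate number of scales.
#' @return increasing integer vector of scales.
#' @export
dfaScales <- function(n, sMin = 6L, sMax = floor(n / 4), nScales = 20L) {
  if (sMax < sMin)
    stop("series too short for the requested scale range", call. = FALSE)
  unique(round(2^seq(log2(sMin), log2(sMax), length.out = nScales)))
}

#' DFA fluctuation function
#'
#' Computes F(s) = sqrt(mean over all 2*Ns segments of the detrended
#' variance), where the profile is split into Ns = floor(N/s) nonoverlapping
#' length-s segments from the start and another Ns from the end, and an
#' order-m polynomial (fit on within-segment index 1..s) is subtracted in
#' each. For a fractal series F(s) ~ s^H.
#'
#' @param series numeric vector.
#' @param scales increasing integer scales; each must satisfy
#'   s > m + 1 and 2 * s <= length(series).
#' @param m polynomial detrending order (default 2).
#' @return A \linkS4class{FluctuationCurve}.
#' @examples
#' x <- generateFGN(0.5, 1024, seed = 1)
#' fitScaling(dfaFluctuation(x))
#' @export
dfaFluctuation <- function(series, scales = dfaScales(length(series)),
                           m = 2L) {
  m <- as.integer(m)
  scales <- as.integer(scales)
  N <- length(series)
  for (s in scales) {
    if (s <= m + 1L)
      stop(sprintf("scale %d too small for detrending order %d", s, m),
           call. = FALSE)
    if (2L * s > N)
      stop(sprintf("scale %d too large for series length %d", s, N),
           call. = FALSE)
  }
  X <- dfaProfile(series)
  vals <- vapply(scales, function(s) {
    R <- segmentResiduals(X, s, m)
    sqrt(mean(colMeans(R^2)))
  }, numeric(1))
  new("FluctuationCurve", scales = as.numeric(scales), values = vals,
      detrendOrder = m)
}

#' Fit a power-law scaling exponent to a curve
#'
#' Ordinary least squares of log2(value) on log2(scale) over the points
#' whose abscissa falls in `fitRange` (inclusive; default: the whole curve).
#' Fluctuation curves yield the Hurst exponent H (the slope); spectrum
#' curves yield the spectral exponent beta = -slope, so beta >= 0 for
#' decaying spectra. Zero values cannot enter the log fit and are excluded
#' with a warning.
#'
#' @param curve a \linkS4class{FluctuationCurve} or
#'   \linkS4class{SpectrumCurve}.
#' @param fitRange numeric length 2, (min, max) of s or f; NULL = full.
#' @return A \linkS4class{ScalingFit}.
#' @export
#' @aliases fitScaling,ScalingCurve-method
setMethod("fitScaling", "ScalingCurve", function(curve, fitRange = NULL) {
  if (is.null(fitRange))
    fitRange <- range(curve@scales)
  keep <- curve@scales >= fitRange[1] & curve@scales <= fitRange[2]
  if (any(curve@values[keep] <= 0)) {
    warning("excluding non-positive curve values from the log-log fit")
    keep <- keep & curve@values > 0
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 usable points in the fit range", call. = FALSE)
  lx <- log2(curve@scales[keep])
  ly <- log2(curve@values[keep])
  fit <- lm(ly ~ lx)
  # exact power laws fit perfectly; summary.lm's warning about that is noise
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2L])
  spectral <- is(curve, "SpectrumCurve")
  new("ScalingFit",
      exponent = if (spectral) -slope else slope,
      stderr = unname(sm$coefficients[2L, 2L]),
      rSquared = if (is.null(sm$r.squared)) NA_real_ else
        min(max(sm$r.squared, 0), 1),
      fitRange = range(curve@scales[keep]),
      kind = if (spectral) "spectral" else "hurst")
})

#' @rdname scalingExponent
#' @export
#' @aliases scalingExponent,ScalingFit-method
setMethod("scalingExponent", "ScalingFit", function(x) x@exponent)

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: %s = %.4f (se %.4f, R2 %.4f), range [%g, %g]\n",
              if (object@kind == "hurst") "H" else "beta",
              object@exponent, object@stderr, object@rSquared,
              object@fitRange[1], object@fitRange[2]))
})

#' @rdname curveScales
#' @export
#' @aliases curveScales,ScalingCurve-method
setMethod("curveScales", "ScalingCurve", function(x) x@scales)

#' @rdname curveValues
#' @export
#' @aliases curveValues,ScalingCurve-method
setMethod("curveValues", "ScalingCurve", function(x) x@values)

setMethod("show", "FluctuationCurve", function(object) {
  cat(sprintf("FluctuationCurve: %d scales in [%g, %g], m = %d\n",
              length(object@scales), min(object@scales), max(object@scales),
              object@detrendOrder))
})

setMethod("show", "SpectrumCurve", function(object) {
  cat(sprintf("SpectrumCurve: %d frequencies in [%g, %g]\n",
              length(object@scales), min(object@scales), max(object@scales)))
})

#' Estimate the Hurst exponent of a series by DFA
#'
#' Convenience wrapper: fluctuation function then log-log fit.
#'
#' @inheritParams dfaFluctuation
#' @param fitRange passed to \code{\link{fitScaling}}.
#' @return A \linkS4class{ScalingFit} of kind "hurst".
#' @export
dfaHurst <- function(series, scales = dfaScales(length(series)), m = 2L,
                     fitRange = NULL) {
  fitScaling(dfaFluctuation(series, scales, m), fitRange)
}

#' Pointwise average of scaling curves
#'
#' Arithmetic mean of curves sharing an identical scale/frequency grid —
#' the session-averaging step performed before exponent fitting (the
#' exponent of the mean curve, not the mean of per-session exponents).
#'
#' @param curves list of \linkS4class{FluctuationCurve} or all
#'   \linkS4class{SpectrumCurve} objects on one grid.
#' @return a curve of the same class.
#' @export
averageCurves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  cls <- class(curves[[1L]])
  g <- curves[[1L]]@scales
  for (cu in curves) {
    if (!identical(class(cu), cls))
      stop("all curves must be of the same class", call. = FALSE)
    if (!isTRUE(all.equal(cu@scales, g)))
      stop("curves must share an identical scale grid", call. = FALSE)
  }
  vals <- rowMeans(vapply(curves, function(cu) cu@values,
                          numeric(length(g))))
  out <- curves[[1L]]
  out@values <- vals
  out
}
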