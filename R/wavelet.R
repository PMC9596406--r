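# Mexican-hat wavelet scalogram (qualitative, display-oriented).

# Mexican hat (Ricker) wavelet: second derivative of a Gaussian,
# L2-normalised.
mexicanHat <- function(t) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
}

#' Wavelet scalogram of a series
#'
#' Computes W[s, k] = s^(-1/2) * sum_j x_j psi((j - k) / s) with the Mexican
#' hat (second derivative of the Gaussian) as the analysing wavelet, over a
#' grid of scales and all time positions. The series is padded by symmetric
#' reflection at both ends; positions within one wavelet support of an edge
#' are flagged as the boundary cone (slot `boundary`) and should be treated
#' as display-only.
#'
#' @param series numeric vector.
#' @param scales positive wavelet scales in frames; default ~24 log-spaced
#'   values in [2, N/4].
#' @return A \linkS4class{Scalogram}.
#' @examples
#' sc <- waveletScalogram(generatePowerLawSignal(1, 256, seed = 4))
#' dim(sc@amplitudes)
#' @export
waveletScalogram <- function(series,
                             scales = unique(round(2^seq(
                               1, log2(length(series) / 4),
                               length.out = 24)))) {
  n <- length(series)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  scales <- sort(unique(as.numeric(scales)))
  # reflection padding long enough for the widest wavelet support
  # (|t| <= 8: the Mexican hat is ~1e-12 there, keeping the discrete
  # kernel effectively zero-sum so constants are annihilated)
  L <- min(n, as.integer(ceiling(8 * max(scales))))
  xp <- c(series[L:1], series, series[n:(n - L + 1L)])
  W <- matrix(0, length(scales), n)
  B <- matrix(FALSE, length(scales), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    r <- as.integer(ceiling(8 * s))
    off <- -r:r
    kern <- mexicanHat(off / s) / sqrt(s)
    W[i, ] <- vapply(seq_len(n), function(k) {
      j <- k + L + off
      ok <- j >= 1L & j <= n + 2L * L
      sum(xp[j[ok]] * kern[ok])
    }, numeric(1))
    B[i, ] <- (seq_len(n) - 1L) < r | (n - seq_len(n)) < r
  }
  new("Scalogram", scales = scales, positions = as.numeric(seq_len(n)),
      amplitudes = W, boundary = B)
}

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram: %d scales x %d positions (Mexican hat)\n",
              length(object@scales), length(object@positions)))
})
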