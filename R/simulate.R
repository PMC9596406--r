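# Synthetic-data generators: exact-covariance fractional Gaussian noise,
# 1/f^beta spectral synthesis, correlated pairs, multi-region surrogates.

# Eigenvalues of the circulant embedding of the fGn autocovariance
# gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2, embedding size 2M.
fgnCirculantEigenvalues <- function(h, M) {
  k <- 0:M
  g <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  Re(stats::fft(c(g, rev(g[2:M]))))
}

#' Generate exact fractional Gaussian noise
#'
#' Simulates a zero-mean, unit-variance stationary Gaussian series whose
#' autocovariance is exactly that of fractional Gaussian noise with Hurst
#' parameter `h`, by circulant embedding of the autocovariance
#' (Davies-Harte). `h = 0.5` gives i.i.d. Gaussian white noise; `h > 0.5`
#' persistent, `h < 0.5` antipersistent noise.
#'
#' If the circulant embedding of size 2n is not non-negative definite the
#' embedding length is doubled (up to three times) before failing.
#'
#' @param h Hurst exponent, 0 < h < 1.
#' @param n series length, >= 64.
#' @param seed integer seed; identical (h, n, seed) is bit-reproducible.
#' @return numeric vector of length n.
#' @examples
#' x <- generateFGN(0.8, 256, seed = 1)
#' @export
generateFGN <- function(h, n, seed) {
  assertScalarNumeric(h, "h")
  if (h <= 0 || h >= 1)
    stop("'h' must lie in (0, 1); use generatePowerLawSignal for H >= 1",
         call. = FALSE)
  n <- as.integer(n)
  if (n < 64L) stop("'n' must be >= 64", call. = FALSE)

  M <- n
  eig <- fgnCirculantEigenvalues(h, M)
  tries <- 0L
  while (min(eig) < -1e-12 * max(eig) && tries < 3L) {
    M <- 2L * M
    eig <- fgnCirculantEigenvalues(h, M)
    tries <- tries + 1L
  }
  if (min(eig) < -1e-12 * max(eig))
    stop(sprintf(paste0(
      "circulant embedding not non-negative definite for h=%g, n=%d, ",
      "even after doubling the embedding length to %d"), h, n, 2L * M),
      call. = FALSE)
  eig <- pmax(eig, 0)

  m <- 2L * M
  withSeed(seed, {
    a0 <- stats::rnorm(1)
    aM <- stats::rnorm(1)
    u <- stats::rnorm(M - 1L)
    v <- stats::rnorm(M - 1L)
    W <- complex(m)
    W[1L] <- sqrt(eig[1L] / m) * a0
    W[M + 1L] <- sqrt(eig[M + 1L] / m) * aM
    k <- seq_len(M - 1L)
    W[k + 1L] <- sqrt(eig[k + 1L] / (2 * m)) * complex(real = u, imaginary = v)
    W[m - k + 1L] <- Conj(W[k + 1L])
    Re(stats::fft(W))[seq_len(n)]
  })
}

#' Generate a 1/f^beta signal by spectral synthesis
#'
#' Constructs a real series whose Fourier amplitudes are proportional to
#' f^(-beta/2) with i.i.d. uniform phases, then standardises it to zero mean
#' and unit variance. The periodogram's log-log slope over the synthesis band
#' is -beta. This is the route to nonstationary signals with DFA exponent
#' H = (beta + 1)/2 > 1, which stationary fractional Gaussian noise cannot
#' reach.
#'
#' @param beta spectral exponent, 0 <= beta <= 3.
#' @param n series length, >= 64.
#' @param seed integer seed.
#' @return numeric vector of length n.
#' @examples
#' pink <- generatePowerLawSignal(1, 1024, seed = 2)
#' @export
generatePowerLawSignal <- function(beta, n, seed) {
  assertScalarNumeric(beta, "beta", lo = 0, hi = 3)
  n <- as.integer(n)
  if (n < 64L) stop("'n' must be >= 64", call. = FALSE)
  half <- (n - 1L) %/% 2L
  x <- withSeed(seed, {
    phi <- stats::runif(half, 0, 2 * pi)
    X <- complex(n)
    amp <- (seq_len(half))^(-beta / 2)
    X[1L + seq_len(half)] <- amp * exp(1i * phi)
    X[n + 1L - seq_len(half)] <- Conj(X[1L + seq_len(half)])
    if (n %% 2L == 0L) {
      # Nyquist bin must be real for a real series
      X[n / 2L + 1L] <- (n / 2L)^(-beta / 2) *
        sign(stats::rnorm(1))
    }
    Re(stats::fft(X, inverse = TRUE))
  })
  (x - mean(x)) / stats::sd(x)
}

#' Generate a correlated pair of fractional Gaussian noises
#'
#' Mixes a shared fGn component into an independent stream so that each
#' marginal is exactly fGn(h) and the expected Pearson correlation between
#' the pair equals `rhoTarget`: y = rho * x + sqrt(1 - rho^2) * e with x, e
#' independent fGn(h). `rhoTarget = 1` returns y identical to x,
#' `rhoTarget = -1` returns y = -x.
#'
#' @param h Hurst exponent of both marginals, 0 < h < 1.
#' @param rhoTarget target Pearson correlation in [-1, 1].
#' @param n series length, >= 64.
#' @param seed integer seed.
#' @return list with numeric elements `x` and `y`.
#' @export
generateCoupledPair <- function(h, rhoTarget, n, seed) {
  assertScalarNumeric(rhoTarget, "rhoTarget", lo = -1, hi = 1)
  s <- childSeeds(seed, 2L)
  x <- generateFGN(h, n, s[1L])
  e <- generateFGN(h, n, s[2L])
  y <- rhoTarget * x + sqrt(1 - rhoTarget^2) * e
  list(x = x, y = y)
}

#' Specify a synthetic multi-region session
#'
#' The default spec emulates the structure of a 116-region AAL session:
#' TR = 1.8 s, 400 frames, per-region Hurst targets spanning 0.5-1.2, and
#' eight equal-size region blocks each sharing a latent component at
#' coupling level c = 0.6.
#'
#' @param nRegions number of regions.
#' @param nFrames number of frames (>= 64).
#' @param tr repetition time, seconds.
#' @param hurst per-region target Hurst exponent; scalar (recycled) or
#'   length-nRegions vector, each in (0, 1.5). Targets >= 1 are synthesised
#'   as 1/f^beta signals with beta = 2H - 1.
#' @param blocks block id per region (integer, recycled); regions sharing a
#'   block id receive a common latent component.
#' @param blockCorrelation Pearson coupling level c in [0, 1], one per block
#'   id (scalar recycled).
#' @param regionLabels region names; defaults to ROI001, ROI002, ...
#' @param seed integer seed.
#' @return A \linkS4class{SurrogateSpec}.
#' @export
surrogateSpec <- function(nRegions = 116L, nFrames = 400L, tr = 1.8,
                          hurst = seq(0.5, 1.2, length.out = nRegions),
                          blocks = rep(seq_len(8L),
                                       length.out = nRegions),
                          blockCorrelation = 0.6,
                          regionLabels = sprintf("ROI%03d",
                                                 seq_len(nRegions)),
                          seed = 1L) {
  nRegions <- as.integer(nRegions)
  blocks <- as.integer(rep_len(blocks, nRegions))
  ids <- sort(unique(blocks))
  blocks <- match(blocks, ids)  # canonical 1..nBlocks
  blockCorrelation <- rep_len(as.numeric(blockCorrelation),
                              length(ids))
  new("SurrogateSpec", nRegions = nRegions, nFrames = as.integer(nFrames),
      tr = as.numeric(tr), hurst = rep_len(as.numeric(hurst), nRegions),
      blocks = blocks, blockCorrelation = blockCorrelation,
      regionLabels = as.character(regionLabels), seed = as.integer(seed))
}

setMethod("show", "SurrogateSpec", function(object) {
  cat(sprintf(paste0(
    "SurrogateSpec: %d regions x %d frames, TR = %g s, H in [%.2f, %.2f], ",
    "%d block(s)\n"), object@nRegions, object@nFrames, object@tr,
    min(object@hurst), max(object@hurst), length(unique(object@blocks))))
})

# One unit-variance scaling component: fGn below H = 1, 1/f^beta at or above.
scalingComponent <- function(h, n, seed) {
  if (h < 1) generateFGN(h, n, seed)
  else generatePowerLawSignal(2 * h - 1, n, seed)
}

#' Generate a surrogate multi-region session
#'
#' Each region r in block b is synthesised as
#' x_r = sqrt(1 - c_b) * e_r + sqrt(c_b) * z_b, where e_r is an independent
#' scaling component with the region's target Hurst exponent and z_b is a
#' latent component shared by the block (generated at the block's mean
#' Hurst target). Within-block Pearson correlations are c_b in expectation;
#' between-block correlations are 0.
#'
#' @param spec a \linkS4class{SurrogateSpec}.
#' @return A \linkS4class{ROITimeSeries} of dimension nFrames x nRegions.
#' @examples
#' x <- generateROISurrogate(surrogateSpec(nRegions = 6, nFrames = 128))
#' dim(boldValues(x))
#' @export
generateROISurrogate <- function(spec) {
  stopifnot(is(spec, "SurrogateSpec"))
  validObject(spec)
  nb <- length(unique(spec@blocks))
  seeds <- childSeeds(spec@seed, spec@nRegions + nb)
  latent <- vapply(seq_len(nb), function(b) {
    hb <- mean(spec@hurst[spec@blocks == b])
    scalingComponent(hb, spec@nFrames, seeds[spec@nRegions + b])
  }, numeric(spec@nFrames))
  vals <- vapply(seq_len(spec@nRegions), function(r) {
    cb <- spec@blockCorrelation[spec@blocks[r]]
    e <- scalingComponent(spec@hurst[r], spec@nFrames, seeds[r])
    sqrt(1 - cb) * e + sqrt(cb) * latent[, spec@blocks[r]]
  }, numeric(spec@nFrames))
  ROITimeSeries(vals, tr = spec@tr, regionLabels = spec@regionLabels,
                provenance = c(source = "surrogate",
                               seed = as.character(spec@seed)))
}

#' Randomly shuffle a series
#'
#' Applies a uniformly random permutation to the values, preserving the
#' multiset of values exactly while destroying all temporal correlations
#' (the DFA exponent of any shuffled series is 0.5).
#'
#' @param series numeric vector.
#' @param seed integer seed.
#' @return numeric vector, a permutation of `series`.
#' @export
shuffleSeries <- function(series, seed) {
  if (any(!is.finite(series)))
    stop("'series' must be finite", call. = FALSE)
  withSeed(seed, series[sample.int(length(series))])
}
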