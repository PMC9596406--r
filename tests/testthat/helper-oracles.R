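# Independent brute-force oracles: explicit loops and generic least squares,
# no code shared with the package implementation.

# Profile: cumulative sum of mean-centred values.
oracleProfile <- function(x) cumsum(x - mean(x))

# Per-segment detrended products of two profiles over the both-ends
# segmentation: forward segments (nu - 1) * s + k, backward segments
# anchored at the end, N - j * s + k. Independent polynomial fits per
# segment via lm on within-segment index 1..s.
oracleSegmentCov <- function(x, y, s, m = 2) {
  X <- oracleProfile(x); Y <- oracleProfile(y)
  N <- length(X); Ns <- N %/% s
  k <- seq_len(s)
  out <- numeric(2 * Ns)
  segIdx <- function(nu) {
    if (nu <= Ns) (nu - 1) * s + k else N - (nu - Ns) * s + k
  }
  for (nu in seq_len(2 * Ns)) {
    idx <- segIdx(nu)
    rx <- residuals(lm(X[idx] ~ poly(k, m, raw = TRUE)))
    ry <- residuals(lm(Y[idx] ~ poly(k, m, raw = TRUE)))
    out[nu] <- mean(rx * ry)
  }
  out
}

# DFA fluctuation function assembled from the per-segment variances.
oracleDFA <- function(x, scales, m = 2) {
  vapply(scales, function(s) sqrt(mean(oracleSegmentCov(x, x, s, m))),
         numeric(1))
}

# q-th order covariance and rho(q, s) from the oracle segments.
oracleQCov <- function(x, y, s, q, m = 2) {
  v <- oracleSegmentCov(x, y, s, m)
  mean(sign(v) * abs(v)^(q / 2))
}
oracleRho <- function(x, y, s, q = 1, m = 2) {
  oracleQCov(x, y, s, q, m) /
    sqrt(oracleQCov(x, x, s, q, m) * oracleQCov(y, y, s, q, m))
}

# Eigenvalues of a small symmetric matrix via the characteristic
# polynomial: Faddeev-LeVerrier coefficients, then polyroot.
oracleEigenvalues <- function(M) {
  n <- nrow(M)
  cfs <- numeric(n + 1)  # cfs[k+1] = coefficient of lambda^(n-k)
  cfs[1] <- 1
  Mk <- diag(n)
  for (k in seq_len(n)) {
    Mk <- M %*% Mk
    ck <- -sum(diag(Mk)) / k
    cfs[k + 1] <- ck
    Mk <- Mk + ck * diag(n)
  }
  r <- polyroot(rev(cfs))
  sort(Re(r), decreasing = TRUE)
}

# A DCCMatrix built directly from given symmetric values (tests only).
makeDCC <- function(v, labels = NULL, method = "rho_q") {
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(v)))
  dimnames(v) <- list(labels, labels)
  new("DCCMatrix", values = v, method = method, q = 1, s = 10,
      provenance = character())
}
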