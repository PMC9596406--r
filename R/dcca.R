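# Detrended cross-correlation analysis: per-segment detrended covariances,
# the q-th order covariance, rho(q, s), and region x region matrices.

#' Per-segment detrended covariance of two series
#'
#' Computes the signed detrended covariance F2_xy(nu, s) for every segment
#' nu = 1..2*Ns of the both-ends segmentation (Ns = floor(N/s) forward
#' segments from the start, Ns backward segments anchored at the end):
#' profiles of x and y are detrended per segment by order-m polynomials
#' (fit on within-segment index 1..s, independently for each profile) and
#' the mean product of residuals is taken. With y = x this reduces to the
#' DFA per-segment detrended variance; covariances, unlike variances, may
#' be negative.
#'
#' @param x,y numeric vectors of equal length N >= 2s.
#' @param s segment length (scale) in frames.
#' @param m polynomial detrending order (default 2, shared with DFA).
#' @return numeric vector of 2*Ns signed values.
#' @export
detrendedCovariance <- function(x, y, s, m = 2L) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  s <- as.integer(s)
  if (s <= m + 1L) stop("scale too small for the detrending order",
                        call. = FALSE)
  if (2L * s > length(x))
    stop(sprintf("scale %d too large for series length %d", s, length(x)),
         call. = FALSE)
  Rx <- segmentResiduals(dfaProfile(x), s, m)
  Ry <- segmentResiduals(dfaProfile(y), s, m)
  colMeans(Rx * Ry)
}

#' q-th order detrended covariance function
#'
#' The sign-preserving power mean over all 2*Ns segments:
#' F^q_xy(s) = mean_nu sign(F2_xy(nu, s)) |F2_xy(nu, s)|^(q/2). The
#' parameter q filters fluctuation amplitudes: q < 2 damps large-amplitude
#' segments, q > 2 emphasises them; q = 2 recovers the plain mean of the
#' per-segment covariances.
#'
#' @inheritParams detrendedCovariance
#' @param q filter order, q > 0 (default 1).
#' @return scalar F^q_xy(s).
#' @export
qCovariance <- function(x, y, s, q = 1, m = 2L) {
  assertScalarNumeric(q, "q", lo = .Machine$double.xmin)
  v <- detrendedCovariance(x, y, s, m)
  mean(sign(v) * abs(v)^(q / 2))
}

#' q-dependent detrended cross-correlation coefficient rho(q, s)
#'
#' rho(q, s) = F^q_xy(s) / sqrt(F^q_xx(s) * F^q_yy(s)). For q = 1 the
#' coefficient is bounded in [-1, 1] and reads like a Pearson correlation
#' restricted to time scale s. Degenerate inputs (vanishing detrended
#' variance, e.g. constant series) raise an error rather than returning a
#' silent value.
#'
#' @inheritParams qCovariance
#' @param s scale in frames (default 10).
#' @return scalar coefficient.
#' @examples
#' p <- generateCoupledPair(0.8, 0.6, 512, seed = 5)
#' rhoQ(p$x, p$y, s = 10)
#' @export
rhoQ <- function(x, y, s = 10L, q = 1, m = 2L) {
  fxx <- qCovariance(x, x, s, q, m)
  fyy <- qCovariance(y, y, s, q, m)
  if (fxx <= 0 || fyy <= 0)
    stop("undefined correlation: a series has vanishing detrended variance",
         call. = FALSE)
  qCovariance(x, y, s, q, m) / sqrt(fxx * fyy)
}

#' Region x region correlation matrix
#'
#' All pairwise coefficients between the regional series of a session:
#' either rho(q, s) (per-segment detrended covariances computed once per
#' region and combined per unordered pair) or plain Pearson correlation.
#'
#' @param x a \linkS4class{ROITimeSeries} (>= 2 regions, N >= 2s frames).
#' @param method "rho_q" or "pearson".
#' @param q,s,m rho_q parameters (defaults q = 1, s = 10 frames, m = 2).
#' @param provenance named character tags stored with the matrix.
#' @return A \linkS4class{DCCMatrix}.
#' @examples
#' x <- generateROISurrogate(surrogateSpec(nRegions = 5, nFrames = 128))
#' correlationMatrix(x)
#' @export
correlationMatrix <- function(x, method = c("rho_q", "pearson"), q = 1,
                              s = 10L, m = 2L, provenance = character()) {
  stopifnot(is(x, "ROITimeSeries"))
  method <- match.arg(method)
  v <- boldValues(x)
  p <- ncol(v)
  if (p < 2L) stop("need at least 2 regions", call. = FALSE)
  labels <- regionLabels(x)

  if (method == "pearson") {
    sds <- apply(v, 2L, sd)
    if (any(sds == 0))
      stop("degenerate (constant) region: ",
           paste(labels[sds == 0], collapse = ", "), call. = FALSE)
    vals <- cor(v)
  } else {
    s <- as.integer(s)
    if (2L * s > nrow(v))
      stop("series too short for scale s", call. = FALSE)
    N <- nrow(v)
    Ns <- N %/% s
    # per-region residual stacks: s x 2Ns each
    R <- array(0, dim = c(s, 2L * Ns, p))
    for (j in seq_len(p))
      R[, , j] <- segmentResiduals(dfaProfile(v[, j]), s, m)
    # per-segment covariance matrices, sign-preserving q/2 power, averaged
    G <- matrix(0, p, p)
    for (nu in seq_len(2L * Ns)) {
      P <- crossprod(R[, nu, ]) / s
      G <- G + sign(P) * abs(P)^(q / 2)
    }
    G <- G / (2L * Ns)
    d <- diag(G)
    if (any(d <= 0))
      stop("degenerate region (vanishing detrended variance): ",
           paste(labels[d <= 0], collapse = ", "), call. = FALSE)
    vals <- G / sqrt(outer(d, d))
    diag(vals) <- 1
  }
  dimnames(vals) <- list(labels, labels)
  new("DCCMatrix", values = vals, method = method,
      q = if (method == "rho_q") q else NA_real_,
      s = if (method == "rho_q") as.numeric(s) else NA_real_,
      provenance = provenance)
}

#' @rdname dccValues
#' @export
#' @aliases dccValues,DCCMatrix-method
setMethod("dccValues", "DCCMatrix", function(x) x@values)

#' @rdname provenance
#' @export
#' @aliases provenance,DCCMatrix-method
setMethod("provenance", "DCCMatrix", function(x) x@provenance)

setMethod("show", "DCCMatrix", function(object) {
  cat(sprintf("DCCMatrix (%s%s): %d x %d regions\n", object@method,
              if (object@method == "rho_q")
                sprintf(", q=%g, s=%g", object@q, object@s) else "",
              nrow(object@values), ncol(object@values)))
  if (length(object@provenance))
    cat("provenance:", paste(names(object@provenance), object@provenance,
                             sep = "=", collapse = ", "), "\n")
})

#' Elementwise mean of correlation matrices
#'
#' Averages matrices over subjects (or sessions) sharing region ordering
#' and method; used to build the per-condition group-mean matrices that
#' feed \code{\link{conditionDifferenceProfile}}.
#'
#' @param matrices list of \linkS4class{DCCMatrix} objects.
#' @return A \linkS4class{DCCMatrix} with the same method/q/s tags.
#' @export
averageDCC <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1L]]
  acc <- matrix(0, nrow(ref@values), ncol(ref@values))
  for (mobj in matrices) {
    if (!identical(rownames(mobj@values), rownames(ref@values)) ||
        !identical(mobj@method, ref@method))
      stop("matrices must share region ordering and method", call. = FALSE)
    acc <- acc + mobj@values
  }
  out <- ref
  out@values <- acc / length(matrices)
  dimnames(out@values) <- dimnames(ref@values)
  out
}

#' Per-region condition-difference profile
#'
#' Given subject-averaged correlation matrices per condition, computes for
#' each non-reference condition c and region i the mean over all other
#' regions j of |<rho>_c[i, j] - <rho>_ref[i, j]| (diagonal excluded): a
#' per-region summary of how much a condition reorganises that region's
#' correlations relative to the reference (typically resting state).
#'
#' @param meanMatrices named list of \linkS4class{DCCMatrix} objects, one
#'   per condition, sharing region ordering.
#' @param reference name of the reference condition in `meanMatrices`.
#' @return data.frame with columns condition, region, score.
#' @export
conditionDifferenceProfile <- function(meanMatrices, reference) {
  if (!reference %in% names(meanMatrices))
    stop("reference condition '", reference, "' not found", call. = FALSE)
  ref <- meanMatrices[[reference]]@values
  out <- list()
  for (cond in setdiff(names(meanMatrices), reference)) {
    v <- meanMatrices[[cond]]@values
    if (!identical(rownames(v), rownames(ref)))
      stop("matrices must share region ordering", call. = FALSE)
    D <- abs(v - ref)
    diag(D) <- 0
    out[[cond]] <- data.frame(
      condition = cond, region = rownames(ref),
      score = rowSums(D) / (ncol(D) - 1L),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read / write a labelled square correlation matrix as TSV
#'
#' First column holds region labels, remaining columns the matrix with
#' region labels as header.
#'
#' @param x a \linkS4class{DCCMatrix}.
#' @param path file path.
#' @param method,q,s tags attached on read.
#' @return `readDCCMatrix` returns a \linkS4class{DCCMatrix}.
#' @export
writeDCCMatrix <- function(x, path) {
  v <- x@values
  hdr <- paste(c("region", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], formatNum(v[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeDCCMatrix
#' @export
readDCCMatrix <- function(path, method = "rho_q", q = 1, s = 10) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1L]]
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- labels
  storage.mode(v) <- "double"
  # symmetrise away round-trip formatting noise and restore the exact
  # unit diagonal
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new("DCCMatrix", values = v, method = method, q = q, s = s,
      provenance = character())
}
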