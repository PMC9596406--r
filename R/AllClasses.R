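#' ROITimeSeries: regional BOLD signals for one session
#'
#' An S4 container for a frames x regions matrix of BOLD signals sampled at a
#' fixed repetition time (TR). Internally the class extends
#' \linkS4class{SummarizedExperiment} with regions as rows (features) and
#' acquisition frames as columns, one assay named \code{"bold"}. The TR in
#' seconds and free-text provenance tags (subject, time of day, task, phase)
#' live in \code{metadata()}.
#'
#' Use \code{\link{ROITimeSeries}} to construct, \code{\link{boldValues}} to
#' retrieve the frames x regions matrix, \code{\link{repetitionTime}} and
#' \code{\link{regionLabels}} for the acquisition parameters.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases ROITimeSeries-class
#' @exportClass ROITimeSeries
setClass("ROITimeSeries", contains = "SummarizedExperiment")

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  if (!"bold" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'bold' is required")
  else {
    a <- SummarizedExperiment::assay(object, "bold")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "BOLD values must be finite and non-missing")
  }
  tr <- S4Vectors::metadata(object)$tr
  if (is.null(tr) || !is.numeric(tr) || length(tr) != 1L || tr <= 0)
    msg <- c(msg, "metadata 'tr' must be a single positive number (seconds)")
  lb <- rownames(object)
  if (is.null(lb) || anyDuplicated(lb))
    msg <- c(msg, "region labels must be present and unique")
  if (length(msg)) msg else TRUE
})

#' EventSchedule: trial event records driving phase segmentation
#'
#' Ordered trial events (onset and duration in seconds, trial_type in
#' \code{{"encoding", "retrieval"}}), the information carried by a BIDS-style
#' events table. Onsets are strictly increasing within each trial type and
#' events never overlap in time.
#'
#' @slot onset numeric, event onsets in seconds.
#' @slot duration numeric, event durations in seconds (> 0).
#' @slot trialType character, one of "encoding" or "retrieval" per event.
#' @aliases EventSchedule-class
#' @exportClass EventSchedule
setClass("EventSchedule",
  representation(onset = "numeric", duration = "numeric",
                 trialType = "character"))

setValidity("EventSchedule", function(object) {
  msg <- character()
  n <- length(object@onset)
  if (length(object@duration) != n || length(object@trialType) != n)
    msg <- c(msg, "onset, duration and trialType must have equal length")
  if (any(!is.finite(object@onset)) || any(!is.finite(object@duration)))
    msg <- c(msg, "onsets and durations must be finite")
  if (any(object@duration <= 0))
    msg <- c(msg, "durations must be positive")
  bad <- setdiff(unique(object@trialType), c("encoding", "retrieval"))
  if (length(bad))
    msg <- c(msg, paste0("unknown trial type(s): ", paste(bad, collapse = ", ")))
  for (ty in unique(object@trialType)) {
    o <- object@onset[object@trialType == ty]
    if (is.unsorted(o, strictly = TRUE))
      msg <- c(msg, sprintf("onsets must be strictly increasing within '%s'", ty))
  }
  if (n > 1L) {
    o <- order(object@onset)
    ends <- object@onset[o] + object@duration[o]
    if (any(ends[-n] > object@onset[o][-1L] + 1e-9))
      msg <- c(msg, "events must not overlap in time")
  }
  if (length(msg)) msg else TRUE
})

#' ScalingCurve: a scale-dependent summary curve
#'
#' Virtual parent of \linkS4class{FluctuationCurve} (DFA fluctuation function
#' F(s)) and \linkS4class{SpectrumCurve} (periodogram S(f)). Both are a
#' strictly increasing abscissa grid with non-negative values, and both admit
#' a power-law fit via \code{\link{fitScaling}}.
#'
#' @slot scales numeric, strictly increasing scale (frames) or frequency grid.
#' @slot values numeric, non-negative curve values, same length as scales.
#' @aliases ScalingCurve-class
#' @exportClass ScalingCurve
setClass("ScalingCurve",
  representation("VIRTUAL", scales = "numeric", values = "numeric"))

setValidity("ScalingCurve", function(object) {
  msg <- character()
  if (length(object@scales) != length(object@values))
    msg <- c(msg, "scales and values must have equal length")
  if (is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing")
  if (any(object@values < 0))
    msg <- c(msg, "curve values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname ScalingCurve-class
#' @slot detrendOrder integer, DFA polynomial detrending order m.
#' @aliases FluctuationCurve-class
#' @exportClass FluctuationCurve
setClass("FluctuationCurve", contains = "ScalingCurve",
  representation(detrendOrder = "integer"))

#' @rdname ScalingCurve-class
#' @aliases SpectrumCurve-class
#' @exportClass SpectrumCurve
setClass("SpectrumCurve", contains = "ScalingCurve")

#' ScalingFit: an estimated scaling exponent
#'
#' The result of a log-log ordinary-least-squares fit to a
#' \linkS4class{ScalingCurve}: a Hurst exponent H (fluctuation curves,
#' F(s) ~ s^H) or a spectral exponent beta (spectrum curves, S(f) ~ f^-beta),
#' with its standard error, R-squared and the fitted scale range.
#'
#' @slot exponent numeric, the estimate (H or beta; dimensionless).
#' @slot stderr numeric, regression standard error of the exponent.
#' @slot rSquared numeric in [0, 1].
#' @slot fitRange numeric length 2, (min, max) of the fitted s or f values.
#' @slot kind character, "hurst" or "spectral".
#' @aliases ScalingFit-class
#' @exportClass ScalingFit
setClass("ScalingFit",
  representation(exponent = "numeric", stderr = "numeric",
                 rSquared = "numeric", fitRange = "numeric",
                 kind = "character"))

setValidity("ScalingFit", function(object) {
  msg <- character()
  if (!object@kind %in% c("hurst", "spectral"))
    msg <- c(msg, "kind must be 'hurst' or 'spectral'")
  if (length(object@fitRange) != 2L || object@fitRange[1] > object@fitRange[2])
    msg <- c(msg, "fitRange must be an ordered (min, max) pair")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Scalogram: wavelet-transform amplitudes over scale and position
#'
#' @slot scales numeric, analysed wavelet scales (frames).
#' @slot positions numeric, time positions k (frames).
#' @slot amplitudes matrix |scales| x |positions| of real W[s, k].
#' @slot boundary logical matrix of the same shape flagging the cone of
#'   influence, i.e. entries within one wavelet support of the series edges
#'   (display-only; affected by the reflection padding).
#' @aliases Scalogram-class
#' @exportClass Scalogram
setClass("Scalogram",
  representation(scales = "numeric", positions = "numeric",
                 amplitudes = "matrix", boundary = "matrix"))

setValidity("Scalogram", function(object) {
  ok <- identical(dim(object@amplitudes),
                  c(length(object@scales), length(object@positions)))
  if (!ok) return("amplitudes must be |scales| x |positions|")
  if (!identical(dim(object@boundary), dim(object@amplitudes)))
    return("boundary must match amplitudes in shape")
  TRUE
})

#' DCCMatrix: a region x region correlation matrix
#'
#' Symmetric matrix of pairwise coefficients between regional series for one
#' (subject, time-of-day, task, phase) configuration — either the q-dependent
#' detrended cross-correlation coefficient rho(q, s) or ordinary Pearson
#' correlation. Unit diagonal by construction; for q = 1 all entries are
#' bounded in [-1, 1].
#'
#' @slot values numeric matrix, regions x regions, symmetric with unit
#'   diagonal; dimnames are the region labels.
#' @slot method character, "rho_q" or "pearson".
#' @slot q numeric, fluctuation-amplitude filter order (rho_q only).
#' @slot s numeric, time scale in frames (rho_q only).
#' @slot provenance named character, free-text configuration tags.
#' @aliases DCCMatrix-class
#' @exportClass DCCMatrix
setClass("DCCMatrix",
  representation(values = "matrix", method = "character", q = "numeric",
                 s = "numeric", provenance = "character"))

setValidity("DCCMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else {
    if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "matrix must be symmetric to 1e-12")
    if (max(abs(diag(v) - 1)) > 1e-12)
      msg <- c(msg, "diagonal must be exactly 1")
  }
  if (!object@method %in% c("rho_q", "pearson"))
    msg <- c(msg, "method must be 'rho_q' or 'pearson'")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must carry identical row/column region labels")
  if (length(msg)) msg else TRUE
})

#' EigenEnsemble: pooled eigenpairs across configurations
#'
#' Eigenvalue/eigenvector entries pooled over many correlation matrices
#' (one per (subject, TOD, task, phase) configuration), with optional cluster
#' labels from reflection-aware Ward clustering. Entries dropped by
#' deduplication carry label NA; \code{clusterOrder} lists cluster ids sorted
#' by decreasing mean member eigenvalue.
#'
#' @slot values numeric, one eigenvalue per entry.
#' @slot vectors numeric matrix, regions x entries, unit-norm columns.
#' @slot config data.frame with one row per entry; typically columns
#'   subject, tod, task, phase plus a matrix identifier.
#' @slot clusterLabels integer per entry (NA = not clustered or dropped).
#' @slot clusterOrder integer, cluster ids in decreasing mean-eigenvalue order.
#' @aliases EigenEnsemble-class
#' @exportClass EigenEnsemble
setClass("EigenEnsemble",
  representation(values = "numeric", vectors = "matrix",
                 config = "data.frame", clusterLabels = "integer",
                 clusterOrder = "integer"))

setValidity("EigenEnsemble", function(object) {
  msg <- character()
  n <- length(object@values)
  if (ncol(object@vectors) != n)
    msg <- c(msg, "one eigenvector column per eigenvalue required")
  if (nrow(object@config) != n)
    msg <- c(msg, "one config row per entry required")
  if (length(object@clusterLabels) != n)
    msg <- c(msg, "one cluster label per entry required")
  if (n > 0) {
    nrm <- sqrt(colSums(object@vectors^2))
    if (max(abs(nrm - 1)) > 1e-10)
      msg <- c(msg, "eigenvectors must be unit-norm to 1e-10")
  }
  if (length(msg)) msg else TRUE
})

#' SurrogateSpec: recipe for a synthetic multi-region session
#'
#' Describes a surrogate ROI session: number of regions and frames, TR,
#' per-region target Hurst exponents, a partition of regions into correlated
#' blocks with a per-block Pearson coupling level c in [0, 1], and the seed.
#' Identical spec + seed gives bit-identical output.
#'
#' @slot nRegions integer >= 1.
#' @slot nFrames integer >= 64.
#' @slot tr numeric, repetition time in seconds.
#' @slot hurst numeric of length nRegions, target H per region (0 < H < 1.5;
#'   H >= 1 regions are synthesised as nonstationary 1/f^beta signals).
#' @slot blocks integer of length nRegions, block id per region.
#' @slot blockCorrelation numeric, coupling level c per block id.
#' @slot regionLabels character of length nRegions.
#' @slot seed integer.
#' @aliases SurrogateSpec-class
#' @exportClass SurrogateSpec
setClass("SurrogateSpec",
  representation(nRegions = "integer", nFrames = "integer", tr = "numeric",
                 hurst = "numeric", blocks = "integer",
                 blockCorrelation = "numeric", regionLabels = "character",
                 seed = "integer"))

setValidity("SurrogateSpec", function(object) {
  msg <- character()
  if (object@nRegions < 1L) msg <- c(msg, "nRegions must be >= 1")
  if (object@nFrames < 64L) msg <- c(msg, "nFrames must be >= 64")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(object@hurst) != object@nRegions)
    msg <- c(msg, "one Hurst target per region required")
  if (any(object@hurst <= 0 | object@hurst >= 1.5))
    msg <- c(msg, "Hurst targets must lie in (0, 1.5)")
  if (length(object@blocks) != object@nRegions)
    msg <- c(msg, "every region must be assigned exactly one block")
  nb <- length(unique(object@blocks))
  if (length(object@blockCorrelation) != nb)
    msg <- c(msg, "one correlation level per block required")
  if (any(object@blockCorrelation < 0 | object@blockCorrelation > 1))
    msg <- c(msg, "block correlation levels must lie in [0, 1]")
  if (length(object@regionLabels) != object@nRegions ||
      anyDuplicated(object@regionLabels))
    msg <- c(msg, "regionLabels must be unique, one per region")
  if (length(msg)) msg else TRUE
})
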