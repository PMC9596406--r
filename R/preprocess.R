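# Phase segmentation and resting-state control preprocessing.

#' Extract and concatenate stimulus-locked phase segments
#'
#' For every event of the requested phase, the frames whose acquisition
#' start time t = k * TR falls in the half-open window
#' [onset + onsetShift, onset + onsetShift + window) are taken, and the
#' per-event blocks are concatenated in order of event appearance. On the
#' default 60-trial schedule at TR = 1.8 s with the 12 s default window,
#' per-event blocks contain 6 or 7 frames and the concatenation is exactly
#' 400 frames long.
#'
#' @param x a \linkS4class{ROITimeSeries}.
#' @param schedule an \linkS4class{EventSchedule}.
#' @param phase "encoding" or "retrieval".
#' @param window window length in seconds (default 12).
#' @param onsetShift optional shift in seconds applied to every onset, e.g.
#'   a haemodynamic-lag offset (default 0).
#' @return A \linkS4class{ROITimeSeries} with the concatenated frames; TR,
#'   labels and provenance preserved, with a `phase` tag added.
#' @examples
#' x <- generateROISurrogate(surrogateSpec(nRegions = 4, nFrames = 800))
#' sched <- generateEventSchedule()
#' enc <- extractPhaseSegments(x, sched, "encoding")
#' nFrames(enc)  # 400
#' @export
extractPhaseSegments <- function(x, schedule, phase, window = 12.0,
                                 onsetShift = 0) {
  stopifnot(is(x, "ROITimeSeries"), is(schedule, "EventSchedule"))
  phase <- match.arg(phase, c("encoding", "retrieval"))
  tr <- repetitionTime(x)
  onsets <- eventOnsets(schedule, phase)
  idx <- integer()
  for (i in seq_along(onsets)) {
    fr <- frameIndicesInWindow(onsets[i] + onsetShift, window, tr)
    if (length(fr) && max(fr) >= nFrames(x))
      stop(sprintf(
        "window of %s event %d (onset %.2f s) extends past the last frame",
        phase, i, onsets[i]), call. = FALSE)
    idx <- c(idx, fr)
  }
  m <- boldValues(x)[idx + 1L, , drop = FALSE]
  ROITimeSeries(m, tr = tr, regionLabels = regionLabels(x),
                provenance = c(provenance(x), phase = phase))
}

#' Build a shuffled-segment resting-state control
#'
#' Cuts the session into floor(frames / segmentFrames) nonoverlapping
#' consecutive blocks of `segmentFrames` frames (trailing remainder frames
#' dropped) and permutes the block order uniformly at random — the same
#' permutation jointly for all regions, so zero-lag cross-region
#' correlations are exactly preserved while long-range temporal structure
#' beyond the block length is destroyed.
#'
#' @param x a \linkS4class{ROITimeSeries}.
#' @param segmentFrames block length in frames (>= 1, <= frames).
#' @param seed integer seed for the block permutation.
#' @return A \linkS4class{ROITimeSeries} with
#'   floor(frames / segmentFrames) * segmentFrames frames.
#' @export
makeRestControl <- function(x, segmentFrames = 6L, seed = 1L) {
  stopifnot(is(x, "ROITimeSeries"))
  segmentFrames <- as.integer(segmentFrames)
  if (segmentFrames < 1L)
    stop("'segmentFrames' must be >= 1", call. = FALSE)
  n <- nFrames(x)
  if (segmentFrames > n)
    stop(sprintf("'segmentFrames' (%d) exceeds the session length (%d)",
                 segmentFrames, n), call. = FALSE)
  nBlocks <- n %/% segmentFrames
  perm <- withSeed(seed, sample.int(nBlocks))
  rows <- as.vector(vapply(perm, function(b)
    (b - 1L) * segmentFrames + seq_len(segmentFrames), integer(segmentFrames)))
  m <- boldValues(x)[rows, , drop = FALSE]
  ROITimeSeries(m, tr = repetitionTime(x), regionLabels = regionLabels(x),
                provenance = c(provenance(x), control = "shuffled-segments"))
}
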