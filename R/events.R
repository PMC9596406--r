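#' Construct an event schedule
#'
#' @param onset numeric, event onsets in seconds.
#' @param duration numeric, event durations in seconds.
#' @param trialType character, "encoding" or "retrieval" per event.
#' @return An \linkS4class{EventSchedule}.
#' @export
EventSchedule <- function(onset, duration, trialType) {
  o <- order(onset)
  new("EventSchedule", onset = as.numeric(onset)[o],
      duration = as.numeric(duration)[o],
      trialType = as.character(trialType)[o])
}

#' @describeIn EventSchedule number of events.
#' @param x an \linkS4class{EventSchedule}.
#' @export
setMethod("length", "EventSchedule", function(x) length(x@onset))

#' Coerce an event schedule to a BIDS-style data.frame
#'
#' @param x an \linkS4class{EventSchedule}.
#' @param ... ignored.
#' @return data.frame with columns onset, duration, trial_type.
#' @export
setMethod("as.data.frame", "EventSchedule", function(x, ...) {
  data.frame(onset = x@onset, duration = x@duration,
             trial_type = x@trialType, stringsAsFactors = FALSE)
})

setMethod("show", "EventSchedule", function(object) {
  tab <- table(object@trialType)
  cat(sprintf("EventSchedule: %d events (%s), span %.1f s\n",
              length(object@onset),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              if (length(object@onset))
                max(object@onset + object@duration) else 0))
})

#' Onsets of a given trial phase
#'
#' @param schedule an \linkS4class{EventSchedule}.
#' @param phase "encoding" or "retrieval"; NULL for all events.
#' @return numeric vector of onsets in seconds, in order of appearance.
#' @export
eventOnsets <- function(schedule, phase = NULL) {
  stopifnot(is(schedule, "EventSchedule"))
  if (is.null(phase)) return(schedule@onset)
  schedule@onset[schedule@trialType == phase]
}

# 0-based acquisition-frame indices whose start time k*tr falls in the
# half-open window [onset, onset + window). A small relative tolerance keeps
# onsets that are exact multiples of tr on the intended side despite
# floating-point division.
frameIndicesInWindow <- function(onset, window, tr) {
  eps <- 1e-9
  first <- ceiling(onset / tr - eps)
  last <- ceiling((onset + window) / tr - eps) - 1
  if (last < first) integer() else seq.int(first, last)
}

#' Generate the default working-memory trial schedule
#'
#' Builds a deterministic trial grid for a DRM-style working-memory session:
#' one encoding and one retrieval (probe) event per trial. Trials are spaced
#' `trialSpacing` seconds apart and the probe follows encoding onset by
#' `retrievalDelay` seconds (stimulus set, distractor/mask, and delay period
#' in between). Encoding stimulus durations are jittered uniformly over
#' `encodingDurationRange` under `seed`; onsets themselves are deterministic.
#'
#' With the defaults (60 trials, TR = 1.8 s, spacing 22.8 s) the onset phase
#' relative to the TR grid cycles with period 3, so stimulus-locked windows
#' of 12 s contain 7, 7, 6 frames (encoding) and 7, 6, 7 frames (retrieval)
#' in repetition — concatenating to exactly 400 frames per phase over the
#' 60 trials.
#'
#' @param nTrials number of trials (>= 1).
#' @param tr repetition time in seconds.
#' @param timing list with elements `trialSpacing` (s, encoding-to-encoding),
#'   `retrievalDelay` (s, encoding onset to probe onset),
#'   `encodingDurationRange` (s, length-2), `probeDuration` (s).
#' @param seed integer seed for the duration jitter.
#' @return An \linkS4class{EventSchedule}.
#' @examples
#' sched <- generateEventSchedule()
#' table(as.data.frame(sched)$trial_type)
#' @export
generateEventSchedule <- function(nTrials = 60L, tr = 1.8,
                                  timing = list(), seed = 1L) {
  stopifnot(nTrials >= 1L)
  tm <- utils::modifyList(
    list(trialSpacing = 22.8, retrievalDelay = 9.8,
         encodingDurationRange = c(1.2, 1.8), probeDuration = 2.0),
    timing)
  if (tm$retrievalDelay <= max(tm$encodingDurationRange))
    stop("retrieval must start after the encoding stimulus ends",
         call. = FALSE)
  encOnset <- (seq_len(nTrials) - 1) * tm$trialSpacing
  retOnset <- encOnset + tm$retrievalDelay
  encDur <- withSeed(seed, stats::runif(nTrials,
                                        tm$encodingDurationRange[1],
                                        tm$encodingDurationRange[2]))
  EventSchedule(onset = c(encOnset, retOnset),
                duration = c(encDur, rep(tm$probeDuration, nTrials)),
                trialType = rep(c("encoding", "retrieval"), each = nTrials))
}

#' Frames needed to cover a schedule's analysis windows
#'
#' @param schedule an \linkS4class{EventSchedule}.
#' @param tr repetition time in seconds.
#' @param window stimulus-locked window length in seconds.
#' @return integer, the smallest session length (frames) containing every
#'   window of the schedule.
#' @export
requiredFrames <- function(schedule, tr = 1.8, window = 12.0) {
  stopifnot(is(schedule, "EventSchedule"))
  idx <- unlist(lapply(schedule@onset, frameIndicesInWindow,
                       window = window, tr = tr))
  if (!length(idx)) return(0L)
  as.integer(max(idx) + 1L)
}

#' Read / write event schedules as BIDS-style TSV
#'
#' Columns onset, duration, trial_type (tab-separated, header included).
#'
#' @param path file path.
#' @return `readEventSchedule` returns an \linkS4class{EventSchedule};
#'   `writeEventSchedule` invisibly returns `path`.
#' @export
readEventSchedule <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events TSV must have columns onset, duration, trial_type",
         call. = FALSE)
  EventSchedule(df$onset, df$duration, df$trial_type)
}

#' @rdname readEventSchedule
#' @param schedule an \linkS4class{EventSchedule}.
#' @export
writeEventSchedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
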