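#' State-classifier parameters
#'
#' The classifier looks for movement "in a series of frames": a trailing
#' window of `window` frames.  The default window is 3 seconds of frames
#' with zero tolerated moved-frames -- short enough to catch the brief
#' arousals that delimit bouts, long enough to suppress single-frame
#' noise.
#'
#' @param window integer >= 1, window length in frames.
#' @param maxAwakeFramesInWindow integer >= 0, strictly less than
#'   `window`: the number of moved-flags tolerated before the window is
#'   scored awake.
#' @return a [StateParams-class].
#' @export
stateParams <- function(window, maxAwakeFramesInWindow = 0) {
  new("StateParams", window = as.integer(window),
      maxAwakeFramesInWindow = as.integer(maxAwakeFramesInWindow))
}

#' @rdname stateParams
#' @param fps frame rate used to size the default 3-second window.
#' @export
defaultStateParams <- function(fps) {
  stateParams(max(1L, as.integer(round(3 * fps))), 0L)
}

#' Construct a StateSequence
#'
#' @param states character vector of `"ASLEEP"`/`"AWAKE"`/`"UNKNOWN"`.
#' @param fps frames per second.
#' @param subjectId subject identifier.
#' @param duration session duration in seconds (defaults to
#'   `length(states) / fps`).
#' @return a [StateSequence-class].
#' @export
stateSequence <- function(states, fps, subjectId = "subject",
                          duration = length(states) / fps) {
  new("StateSequence", subjectId = as.character(subjectId),
      fps = as.numeric(fps), states = as.character(states),
      duration = as.numeric(duration))
}

#' Classify per-frame asleep/awake states from motion measurements
#'
#' A dog with no detected movement is scored as asleep.  Concretely, for
#' every frame carrying a detection, the moved-flags of the trailing
#' window of `params@window` frames are counted (frames without a
#' detection, and frames whose motion could not be measured, contribute no
#' flag); the frame is `"ASLEEP"` when the count is at most
#' `params@maxAwakeFramesInWindow` and `"AWAKE"` otherwise.  Frames with
#' no detection are `"UNKNOWN"` -- a missing detection is never
#' interpolated.  The first `window - 1` frames, whose trailing window is
#' incomplete, inherit the first state computed from a complete window.
#'
#' @param measurements data frame with columns `frame_index` (0-based) and
#'   `moved` (logical, `NA` when motion could not be measured, e.g. the
#'   first frame of a track), at most one row per frame.  Row order is
#'   irrelevant; rows are sorted by frame.
#' @param params a [StateParams-class].
#' @param fps frames per second.
#' @param duration session duration in seconds; defaults to covering the
#'   last measured frame.
#' @param subjectId subject identifier for the result.
#' @return a [StateSequence-class].
#' @export
classifyStates <- function(measurements, params, fps,
                           duration = (max(measurements$frame_index) + 1) / fps,
                           subjectId = "subject") {
  if (is.null(measurements) || nrow(measurements) == 0L)
    stop("no measurements: cannot classify an empty session")
  m <- measurements[order(measurements$frame_index), , drop = FALSE]
  if (anyDuplicated(m$frame_index))
    stop("at most one measurement per frame per subject")
  n <- as.integer(round(duration * fps))
  if (any(m$frame_index < 0L) || any(m$frame_index >= n))
    stop("measurement frame index outside the session")
  w <- params@window
  tol <- params@maxAwakeFramesInWindow

  present <- logical(n)
  present[m$frame_index + 1L] <- TRUE
  movedv <- numeric(n)
  movedv[m$frame_index + 1L] <- as.numeric(m$moved %in% TRUE)

  cs <- cumsum(movedv)
  i <- seq_len(n)
  cnt <- cs - c(rep(0, min(w, n)), cs[seq_len(n - min(w, n))])
  state <- ifelse(cnt <= tol, "ASLEEP", "AWAKE")

  # frames with an incomplete trailing window inherit the first state
  # computed from a complete one
  if (n >= w && w > 1L) {
    firstFull <- which(present & i >= w)[1L]
    if (!is.na(firstFull))
      state[seq_len(w - 1L)] <- state[firstFull]
  }
  state[!present] <- "UNKNOWN"
  stateSequence(state, fps, subjectId, duration)
}

#' Bridge short UNKNOWN gaps inside sleep
#'
#' By default UNKNOWN frames terminate sleep runs.  This opt-in smoothing
#' relabels UNKNOWN runs of at most `maxSeconds` that are flanked by
#' ASLEEP on both sides as ASLEEP.
#'
#' @param seq a [StateSequence-class].
#' @param maxSeconds maximum gap to bridge, seconds.
#' @return a [StateSequence-class].
#' @export
bridgeUnknown <- function(seq, maxSeconds) {
  s <- seq@states
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "UNKNOWN" && k > 1L && k < length(r$values) &&
        r$values[k - 1L] == "ASLEEP" && r$values[k + 1L] == "ASLEEP" &&
        r$lengths[k] / seq@fps <= maxSeconds)
      s[starts[k]:ends[k]] <- "ASLEEP"
  }
  stateSequence(s, seq@fps, seq@subjectId, seq@duration)
}

#' Extract sleeping bouts from a state sequence
#'
#' A sleeping bout is one maximal episode of sleep delimited by
#' wakefulness, counted regardless of its duration.  Each maximal run of
#' ASLEEP frames yields one bout; UNKNOWN frames break a run.  By default
#' a sleep run touching the start or end of the session also counts as a
#' bout (otherwise overnight sessions that begin or end asleep would be
#' systematically undercounted); set `strictWSW = TRUE` to require
#' wakefulness on both sides.
#'
#' @param seq a [StateSequence-class].
#' @param strictWSW logical; require an AWAKE frame immediately before and
#'   after the run.
#' @param bridgeUnknownMaxS seconds; if > 0, apply [bridgeUnknown()]
#'   first.
#' @return data frame with columns `start`, `end`, `duration` (seconds,
#'   from frame indices / fps); zero rows when there is no sleep.
#' @examples
#' s <- stateSequence(c("AWAKE", "ASLEEP", "AWAKE", "ASLEEP", "ASLEEP",
#'                      "AWAKE"), fps = 1)
#' extractBouts(s)  # two bouts, 1 s and 2 s
#' @export
extractBouts <- function(seq, strictWSW = FALSE, bridgeUnknownMaxS = 0) {
  if (bridgeUnknownMaxS > 0) seq <- bridgeUnknown(seq, bridgeUnknownMaxS)
  s <- seq@states
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "ASLEEP"
  if (strictWSW) {
    prevAwake <- c(FALSE, r$values[-length(r$values)] == "AWAKE")
    nextAwake <- c(r$values[-1L] == "AWAKE", FALSE)
    keep <- keep & prevAwake & nextAwake
  }
  idx <- which(keep)
  out <- data.frame(start = (starts[idx] - 1L) / seq@fps,
                    end = ends[idx] / seq@fps)
  out$duration <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Summarise sleep for one session
#'
#' Durations are frame counts divided by fps; the percentage asleep is
#' taken over known (non-UNKNOWN) time only and is `NA` when the whole
#' session is UNKNOWN.
#'
#' @param seq a [StateSequence-class].
#' @param ... passed to [extractBouts()] (`strictWSW`,
#'   `bridgeUnknownMaxS`).
#' @return a [SleepSummary-class].
#' @export
summarizeSleep <- function(seq, ...) {
  s <- seq@states
  nSleep <- sum(s == "ASLEEP")
  nAwake <- sum(s == "AWAKE")
  nUnknown <- sum(s == "UNKNOWN")
  known <- nSleep + nAwake
  bouts <- extractBouts(seq, ...)
  new("SleepSummary", subjectId = seq@subjectId,
      totalSleepS = nSleep / seq@fps, totalAwakeS = nAwake / seq@fps,
      totalUnknownS = nUnknown / seq@fps,
      observedS = length(s) / seq@fps,
      boutCount = nrow(bouts),
      percentAsleep = if (known > 0) 100 * nSleep / known else NA_real_)
}

#' Format seconds as H:MM:SS
#'
#' Sub-second remainders are truncated, matching the rendering of sleep
#' durations in validation tables.
#'
#' @param seconds numeric, seconds.
#' @return character like `"12:05:56"`.
#' @export
formatHMS <- function(seconds) {
  s <- floor(seconds + 1e-9)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' @rdname formatHMS
#' @param text character in `H:MM:SS` form.
#' @return `parseHMS` returns seconds.
#' @export
parseHMS <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(is.na(p))) stop("not an H:MM:SS string")
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}
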