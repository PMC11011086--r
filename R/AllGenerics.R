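#' Read one frame from a stream
#'
#' @param x a [FrameStream-class].
#' @param index 0-based frame index.
#' @return a [Frame-class].
#' @export
setGeneric("getFrame", function(x, index) standardGeneric("getFrame"))

#' Number of frames in a stream
#' @param x a [FrameStream-class].
#' @export
setGeneric("nframes", function(x) standardGeneric("nframes"))

#' Frames per second
#' @param x a [FrameStream-class] or [StateSequence-class].
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' Run a detector on one frame
#'
#' @param object a [Detector-class] implementation.
#' @param frame a [Frame-class].
#' @return data frame with columns `frame_index`, `subject_id` (`NA` until
#'   assigned by [associateDetections()]), `x_min`, `y_min`, `x_max`,
#'   `y_max` (half-open pixel coordinates, clipped to frame bounds) and
#'   `confidence` in \[0, 1\].  Zero rows when no dog is present.
#' @export
setGeneric("detect", function(object, frame) standardGeneric("detect"))

#' Per-frame states of a sequence
#' @param x a [StateSequence-class].
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Subject identifier
#' @param x a [StateSequence-class] or [SleepSummary-class].
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Session duration in seconds
#' @param x a [StateSequence-class] or [SleepSummary-class].
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))

#' Total sleep in seconds
#' @param x a [SleepSummary-class].
#' @export
setGeneric("totalSleep", function(x) standardGeneric("totalSleep"))

#' Number of sleeping bouts
#' @param x a [SleepSummary-class].
#' @export
setGeneric("boutCount", function(x) standardGeneric("boutCount"))

#' Percentage of known time spent asleep
#' @param x a [SleepSummary-class].
#' @export
setGeneric("percentAsleep", function(x) standardGeneric("percentAsleep"))

#' @describeIn getFrame frames held in memory
setMethod("getFrame", "MemoryFrameStream", function(x, index) {
  .checkFrameIndex(index, x@nframes)
  newFrame(x@frames[[index + 1L]], index, index / x@fps, x@mode)
})

#' @describeIn nframes stream frame count
setMethod("nframes", "FrameStream", function(x) x@nframes)

#' @describeIn fps stream rate
setMethod("fps", "FrameStream", function(x) x@fps)

#' @describeIn fps sequence rate
setMethod("fps", "StateSequence", function(x) x@fps)

setMethod("states", "StateSequence", function(x) x@states)
setMethod("subjectId", "StateSequence", function(x) x@subjectId)
setMethod("subjectId", "SleepSummary", function(x) x@subjectId)
setMethod("sessionDuration", "StateSequence", function(x) x@duration)
setMethod("sessionDuration", "SleepSummary", function(x) x@observedS)
setMethod("totalSleep", "SleepSummary", function(x) x@totalSleepS)
setMethod("boutCount", "SleepSummary", function(x) x@boutCount)
setMethod("percentAsleep", "SleepSummary", function(x) x@percentAsleep)

.checkFrameIndex <- function(index, n) {
  if (length(index) != 1L || is.na(index) || index < 0 || index >= n)
    stop(sprintf("frame index %s out of range [0, %d)", toString(index), n),
         call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "StateSequence", function(object) {
  tab <- table(factor(object@states, levels = .STATES))
  cat(sprintf(
    "StateSequence '%s': %d frames @ %g fps (%.1f s)\n",
    object@subjectId, length(object@states), object@fps, object@duration))
  cat(sprintf("  ASLEEP %d | AWAKE %d | UNKNOWN %d\n",
              tab[["ASLEEP"]], tab[["AWAKE"]], tab[["UNKNOWN"]]))
})

setMethod("show", "SleepSummary", function(object) {
  cat(sprintf("SleepSummary '%s'\n", object@subjectId))
  cat(sprintf("  total sleep   %s (%.0f s)\n",
              formatHMS(object@totalSleepS), object@totalSleepS))
  cat(sprintf("  bouts         %d\n", object@boutCount))
  cat(sprintf("  percent asleep %s\n",
              if (is.na(object@percentAsleep)) "NA (no known time)"
              else sprintf("%.2f%%", object@percentAsleep)))
  cat(sprintf("  observed      %s (unknown %s)\n",
              formatHMS(object@observedS), formatHMS(object@totalUnknownS)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.3f", object@method, object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  if (!is.na(object@p)) cat(sprintf(", p = %.4g", object@p))
  cat(sprintf(" [%ssignificant at alpha = %g]\n",
              if (object@significant) "" else "not ", object@alpha))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf(
    "Scenario: %dx%d px, %g fps, %g s, %d dog(s), %s, seed %d\n",
    object@width, object@height, object@fps, object@duration,
    length(object@dogs), object@mode, object@seed))
})

setMethod("show", "FrameStream", function(object) {
  cat(sprintf("%s: %d frames @ %g fps\n", class(object),
              object@nframes, object@fps))
})
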