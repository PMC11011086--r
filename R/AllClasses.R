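#' @import methods
NULL

.STATES <- c("ASLEEP", "AWAKE", "UNKNOWN")
.MODES <- c("DAY_COLOUR", "NIGHT_GRAY")

#' Frame: a single video frame
#'
#' One image from a recording, together with its position in the stream.
#' Pixel intensities are 8-bit (0--255) stored as a numeric matrix
#' (grayscale) or a height x width x 3 array (colour, RGB channel order).
#' Frame indices are 0-based; the timestamp of frame \eqn{i} in a
#' constant-rate stream is \eqn{i / \mathrm{fps}} seconds from session start.
#' The image origin is the top-left corner, with (row, column) indexing.
#'
#' @slot pixels numeric matrix or 3-d array of intensities in \[0, 255\].
#' @slot index integer frame index, 0-based.
#' @slot timestamp numeric, seconds from session start.
#' @slot mode `"DAY_COLOUR"` or `"NIGHT_GRAY"` (infrared night vision).
#' @export
setClass("Frame",
  representation(pixels = "array", index = "integer",
                 timestamp = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
      msg <- c(msg, "pixels must be a matrix or a h x w x 3 array")
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "pixel values must lie in [0, 255]")
    if (object@index < 0L) msg <- c(msg, "index must be >= 0")
    if (!object@mode %in% .MODES)
      msg <- c(msg, "mode must be DAY_COLOUR or NIGHT_GRAY")
    if (length(msg)) msg else TRUE
  })

#' FrameStream: an ordered source of frames
#'
#' Virtual parent of [DirectoryFrameStream-class] (numbered PNG files on
#' disk) and [MemoryFrameStream-class] (rendered frames held in memory).
#' Frames are addressed by 0-based index via [getFrame()].
#'
#' @slot fps numeric, frames per second (> 0).
#' @slot nframes integer, number of frames in the stream.
#' @export
setClass("FrameStream",
  representation("VIRTUAL", fps = "numeric", nframes = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      msg <- c(msg, "fps must be a single positive number")
    if (object@nframes < 0L) msg <- c(msg, "frame count must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname FrameStream-class
#' @slot path directory the frames were read from.
#' @slot files character vector of frame file paths, in stream order.
#' @slot dim expected (height, width) of every frame; frames that disagree
#'   are a fatal error at read time, naming the offending frame.
#' @export
setClass("DirectoryFrameStream", contains = "FrameStream",
  representation(path = "character", files = "character", dim = "integer"))

#' @rdname FrameStream-class
#' @slot frames list of pixel arrays, one per frame.
#' @slot mode frame mode shared by all frames.
#' @export
setClass("MemoryFrameStream", contains = "FrameStream",
  representation(frames = "list", mode = "character"))

#' MotionParams: tuning of the six-step motion detector
#'
#' Parameters of the frame-differencing pipeline run on the cropped
#' bounding-box content of consecutive frames: Gaussian blur, inter-frame
#' absolute delta, binarization, dilation, and connected-component area.
#' All values are configuration choices of this package (the classical
#' frame-differencing recipe); see the package vignette for rationale.
#'
#' @slot blurKernel odd integer >= 1, Gaussian kernel width in pixels.
#' @slot deltaThreshold integer in \[1, 255\]; delta pixels strictly above
#'   it count as changed.
#' @slot dilateKernel odd integer >= 1, square structuring element width.
#' @slot dilateIterations integer >= 0, dilation repetitions.
#' @slot minComponentArea integer >= 1; connected components smaller than
#'   this (pixels) are ignored as noise.
#' @slot minMotionFraction numeric >= 0; qualifying area, as a fraction of
#'   the crop area, required to flag movement.
#' @export
setClass("MotionParams",
  representation(blurKernel = "integer", deltaThreshold = "integer",
                 dilateKernel = "integer", dilateIterations = "integer",
                 minComponentArea = "integer", minMotionFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@blurKernel < 1L || object@blurKernel %% 2L == 0L)
      msg <- c(msg, "blurKernel must be an odd integer >= 1")
    if (object@deltaThreshold < 1L || object@deltaThreshold > 255L)
      msg <- c(msg, "deltaThreshold must be in [1, 255]")
    if (object@dilateKernel < 1L || object@dilateKernel %% 2L == 0L)
      msg <- c(msg, "dilateKernel must be an odd integer >= 1")
    if (object@dilateIterations < 0L)
      msg <- c(msg, "dilateIterations must be >= 0")
    if (object@minComponentArea < 1L)
      msg <- c(msg, "minComponentArea must be >= 1")
    if (object@minMotionFraction < 0)
      msg <- c(msg, "minMotionFraction must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' StateParams: windowing of the asleep/awake classifier
#'
#' A dog is scored asleep at a frame when the number of moved-flags in the
#' trailing window of `window` frames is at most
#' `maxAwakeFramesInWindow`, and awake otherwise.
#'
#' @slot window integer >= 1, window length in frames.
#' @slot maxAwakeFramesInWindow integer >= 0, strictly less than `window`.
#' @export
setClass("StateParams",
  representation(window = "integer", maxAwakeFramesInWindow = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@window < 1L) msg <- c(msg, "window must be >= 1")
    if (object@maxAwakeFramesInWindow < 0L)
      msg <- c(msg, "maxAwakeFramesInWindow must be >= 0")
    if (object@maxAwakeFramesInWindow >= object@window)
      msg <- c(msg, "maxAwakeFramesInWindow must be < window")
    if (length(msg)) msg else TRUE
  })

#' StateSequence: per-frame behavioural state of one subject
#'
#' One state per frame, each `"ASLEEP"`, `"AWAKE"` or `"UNKNOWN"`
#' (no detection for that frame).  Both the automated pipeline
#' ([classifyStates()]) and the human-observation reader
#' ([readObservationLog()]) produce this class, so the two methods are
#' directly comparable with [frameAgreement()] and [summarizeSleep()].
#'
#' @slot subjectId character identifier of the animal.
#' @slot fps numeric frames per second.
#' @slot states character vector of per-frame states.
#' @slot duration numeric session duration in seconds;
#'   `length(states) == round(duration * fps)`.
#' @export
setClass("StateSequence",
  representation(subjectId = "character", fps = "numeric",
                 states = "character", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
    if (!all(object@states %in% .STATES))
      msg <- c(msg, "states must be ASLEEP, AWAKE or UNKNOWN")
    if (length(object@states) != round(object@duration * object@fps))
      msg <- c(msg, "length(states) must equal round(duration * fps)")
    if (length(msg)) msg else TRUE
  })

#' SleepSummary: per-session sleep metrics for one subject
#'
#' The per-row content of a validation summary table: total sleep, number
#' of sleeping bouts, and percentage of known time spent asleep.
#'
#' @slot subjectId character identifier of the animal.
#' @slot totalSleepS,totalAwakeS,totalUnknownS,observedS numeric seconds;
#'   sleep + awake + unknown equals the observed duration.
#' @slot boutCount integer number of sleeping bouts.
#' @slot percentAsleep numeric, `100 * sleep / (sleep + awake)`; `NA` when
#'   no frame has a known state.
#' @export
setClass("SleepSummary",
  representation(subjectId = "character", totalSleepS = "numeric",
                 totalAwakeS = "numeric", totalUnknownS = "numeric",
                 observedS = "numeric", boutCount = "integer",
                 percentAsleep = "numeric"),
  validity = function(object) {
    msg <- character()
    tot <- object@totalSleepS + object@totalAwakeS + object@totalUnknownS
    if (abs(tot - object@observedS) > 1 + 1e-9) # within one frame interval
      msg <- c(msg, "state totals must sum to the observed duration")
    if (object@boutCount < 0L) msg <- c(msg, "boutCount must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' TestResult: outcome of a significance test
#'
#' @slot statistic numeric test statistic (t, or the corrected
#'   Anderson-Darling A*^2).
#' @slot df numeric degrees of freedom (`NA` where not applicable).
#' @slot p numeric p-value in \[0, 1\] (`NA` for threshold-only decisions).
#' @slot alpha numeric significance level.
#' @slot significant logical decision at `alpha`.
#' @slot method character description.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", p = "numeric",
                 alpha = "numeric", significant = "logical",
                 method = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@p) && (object@p < 0 || object@p > 1))
      msg <- c(msg, "p must lie in [0, 1]")
    if (!is.na(object@p) && object@significant != (object@p < object@alpha))
      msg <- c(msg, "significant must equal (p < alpha)")
    if (length(msg)) msg else TRUE
  })

#' Detector: pluggable per-frame dog detector
#'
#' The detection stage of the pipeline (in deployment, a trained neural
#' network) is represented as an interface: any object with a
#' [detect()] method returning a detection data frame.  Bundled
#' implementations are [GroundTruthDetector-class] (reads the true boxes of
#' a synthetic scenario) and [StaticRoiDetector-class] (a user-configured
#' fixed region, for single-kennel footage).  Network training is out of
#' scope.
#'
#' @export
setClass("Detector", representation("VIRTUAL"))

#' @rdname Detector-class
#' @slot detections data frame in the detection schema (see
#'   [writeDetections()]) holding the true boxes per frame.
#' @slot nframes integer number of frames covered; requesting a frame at or
#'   beyond this is an error.
#' @export
setClass("GroundTruthDetector", contains = "Detector",
  representation(detections = "data.frame", nframes = "integer"))

#' @rdname Detector-class
#' @slot box numeric length-4 bounding box `(x_min, y_min, x_max, y_max)`,
#'   half-open pixel coordinates.
#' @export
setClass("StaticRoiDetector", contains = "Detector",
  representation(box = "numeric"))

#' DogSpec: one synthetic dog
#'
#' Describes a blob dog for the synthetic renderer: a textured ellipse that
#' is displaced every awake frame and static while asleep apart from
#' optional twitches.  The awake step is drawn from a zero-mean symmetric
#' distribution `sign * (awakeMinStep + |N(0, awakeMotionSd)|)` per axis, so
#' that wakefulness always produces perceivable movement -- the statistical
#' structure (motion if and only if awake) that behavioural sleep scoring
#' assumes.
#'
#' @slot size numeric body length in pixels (ellipse axes size/2, size/3).
#' @slot start numeric length-2 start centre `(x, y)` in pixels.
#' @slot schedule data frame with columns `state` (`"ASLEEP"`/`"AWAKE"`) and
#'   `duration` (seconds); durations must sum to the scenario duration.
#' @slot awakeMotionSd numeric pixels/frame, spread of the awake step.
#' @slot awakeMinStep numeric pixels, minimum per-axis awake displacement.
#' @slot territory numeric pixels: the dog's centre stays within this
#'   radius (per axis) of its start position, emulating the confinement
#'   of a kennel pen; `Inf` allows the whole arena.
#' @slot twitchProb numeric in \[0, 1\], per asleep frame.
#' @slot twitchAmplitude numeric pixels, sd of the transient twitch offset.
#' @slot bodyIntensity numeric mean body intensity (0--255).
#' @slot textureSd numeric sd of the frozen body texture.
#' @slot jitterSd numeric sd of the per-awake-frame limb-jitter texture
#'   perturbation.
#' @export
setClass("DogSpec",
  representation(size = "numeric", start = "numeric", schedule = "data.frame",
                 territory = "numeric",
                 awakeMotionSd = "numeric", awakeMinStep = "numeric",
                 twitchProb = "numeric", twitchAmplitude = "numeric",
                 bodyIntensity = "numeric", textureSd = "numeric",
                 jitterSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@size < 6) msg <- c(msg, "size must be >= 6 pixels")
    if (length(object@start) != 2L) msg <- c(msg, "start must be (x, y)")
    if (!all(c("state", "duration") %in% names(object@schedule)))
      msg <- c(msg, "schedule needs columns state, duration")
    else {
      if (!all(object@schedule$state %in% c("ASLEEP", "AWAKE")))
        msg <- c(msg, "schedule states must be ASLEEP or AWAKE")
      if (any(object@schedule$duration <= 0))
        msg <- c(msg, "schedule entries must have positive duration")
    }
    if (object@twitchProb < 0 || object@twitchProb > 1)
      msg <- c(msg, "twitchProb must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' NuisanceSpec: global recording nuisances
#'
#' Camera shake (wind), light flicker (lights switching / mains flicker)
#' and sensor noise, applied to the composited frame after the dogs are
#' drawn.  All zero by default.
#'
#' @slot shakeSd numeric pixels/frame sd of the global translation.
#' @slot flickerAmplitude numeric intensity units of the sinusoidal flicker.
#' @slot flickerPeriod numeric seconds.
#' @slot sensorNoiseSd numeric intensity units of per-pixel Gaussian noise.
#' @export
setClass("NuisanceSpec",
  representation(shakeSd = "numeric", flickerAmplitude = "numeric",
                 flickerPeriod = "numeric", sensorNoiseSd = "numeric"),
  validity = function(object) {
    if (any(c(object@shakeSd, object@flickerAmplitude, object@flickerPeriod,
              object@sensorNoiseSd) < 0))
      "all nuisance magnitudes must be >= 0" else TRUE
  })

#' Scenario: a synthetic recording description
#'
#' @slot width,height integer arena size in pixels.
#' @slot fps numeric frames per second.
#' @slot duration numeric seconds; `duration * fps` must be an integer.
#' @slot seed integer random seed; rendering is deterministic given it.
#' @slot dogs list of [DogSpec-class] (0 to 2 dogs, the range the detection
#'   stage is evaluated on).
#' @slot mode `"DAY_COLOUR"` or `"NIGHT_GRAY"`.
#' @slot nuisance a [NuisanceSpec-class].
#' @export
setClass("Scenario",
  representation(width = "integer", height = "integer", fps = "numeric",
                 duration = "numeric", seed = "integer", dogs = "list",
                 mode = "character", nuisance = "NuisanceSpec"),
  validity = function(object) {
    msg <- character()
    if (object@width < 16L || object@height < 16L)
      msg <- c(msg, "arena must be at least 16 x 16 pixels")
    if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
    nf <- object@duration * object@fps
    if (abs(nf - round(nf)) > 1e-9)
      msg <- c(msg, "duration x fps must be an integer frame count")
    if (length(object@dogs) > 2L)
      msg <- c(msg, "at most 2 dogs per scenario")
    if (!all(vapply(object@dogs, is, logical(1), "DogSpec")))
      msg <- c(msg, "dogs must be DogSpec objects")
    if (!object@mode %in% .MODES)
      msg <- c(msg, "mode must be DAY_COLOUR or NIGHT_GRAY")
    for (i in seq_along(object@dogs)) {
      d <- object@dogs[[i]]
      if (is(d, "DogSpec")) {
        tot <- sum(d@schedule$duration)
        if (abs(tot - object@duration) > 1e-9)
          msg <- c(msg, sprintf(
            "schedule of dog %d sums to %g s, scenario duration is %g s",
            i, tot, object@duration))
        a <- d@size / 2
        if (d@start[1] - a < 1 || d@start[1] + a > object@width - 1 ||
            d@start[2] - a < 1 || d@start[2] + a > object@height - 1)
          msg <- c(msg, sprintf("dog %d exceeds the arena", i))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: what a synthetic scenario really contains
#'
#' @slot detections data frame of true per-frame boxes in the detection
#'   schema (confidence 1).
#' @slot states named list of true [StateSequence-class], one per dog.
#' @slot summaries named list of [SleepSummary-class] derived from the true
#'   state sequences (so the generator's own summary is consistent with
#'   [summarizeSleep()] by construction).
#' @slot scenario the [Scenario-class] that was rendered.
#' @export
setClass("GroundTruth",
  representation(detections = "data.frame", states = "list",
                 summaries = "list", scenario = "Scenario"))

#' PairedSessions: matched system and manual summaries
#'
#' One row per observation session retained for comparison, with the
#' automated and human sleep totals (seconds), percent-of-time values,
#' bout counts, and optional externally supplied percent-difference
#' columns (as printed in a source validation table).
#'
#' @slot data data frame with columns `session`, `sleep_system_s`,
#'   `sleep_manual_s`, `pct_system`, `pct_manual`, `bouts_system`,
#'   `bouts_manual`, `pctdiff_sleep`, `pctdiff_bouts` (the latter four may
#'   be `NA`).
#' @export
setClass("PairedSessions", representation(data = "data.frame"),
  validity = function(object) {
    need <- c("session", "sleep_system_s", "sleep_manual_s", "pct_system",
              "pct_manual", "bouts_system", "bouts_manual",
              "pctdiff_sleep", "pctdiff_bouts")
    miss <- setdiff(need, names(object@data))
    msg <- character()
    if (length(miss))
      msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
    else if (any(is.na(object@data$sleep_system_s)) ||
             any(is.na(object@data$sleep_manual_s)))
      msg <- c(msg, "both summaries must be present for every session")
    if (length(msg)) msg else TRUE
  })

#' ComparisonReport: method-agreement report
#'
#' Produced by [comparisonReport()]: per-session rows, column summaries and
#' the paired tests on sleep duration, percent of time asleep, and bout
#' counts, with Anderson-Darling normality checks of the paired
#' differences.
#'
#' @slot sessions data frame of per-session rendered rows.
#' @slot summaries named list of column summaries (mean/sd/min/max).
#' @slot tests named list of [TestResult-class] or `"identical"` markers.
#' @slot normality named list of [TestResult-class] (or `NA`).
#' @slot alpha numeric significance level used.
#' @export
setClass("ComparisonReport",
  representation(sessions = "data.frame", summaries = "list",
                 tests = "list", normality = "list", alpha = "numeric"))
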