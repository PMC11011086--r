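#' Analyse a session end-to-end
#'
#' Runs the full pipeline on a frame stream: per-frame detection, greedy
#' IoU association of detections into per-dog tracks, the six-step motion
#' measurement on each subject's bounding-box crop (both crops taken at
#' the current frame's box, so box drift does not count as motion),
#' windowed asleep/awake classification, bout extraction and
#' summarisation.  Frames where a subject is not detected are UNKNOWN;
#' the motion of the first detected frame of a track cannot be measured
#' and contributes no moved-flag.
#'
#' @param stream a [FrameStream-class].
#' @param detector a [Detector-class].
#' @param motion a [MotionParams-class].
#' @param state a [StateParams-class]; defaults to a 3-second window at
#'   the stream's frame rate.
#' @param minIou association threshold (default 0.3).
#' @return list with `summaries` (named list of [SleepSummary-class]),
#'   `states` (named list of [StateSequence-class]), and `measurements`
#'   (data frame `frame_index`, `subject_id`, `area`, `moved`).  All
#'   empty when the footage contains no dogs.
#' @export
analyzeSession <- function(stream, detector, motion = motionParams(),
                           state = defaultStateParams(fps(stream)),
                           minIou = 0.3) {
  n <- nframes(stream)
  if (n == 0L) stop("no frames")
  duration <- n / fps(stream)
  prevGray <- NULL
  prevDets <- .emptyDetections()
  nextId <- 1L
  meas <- vector("list", n)
  for (i in seq_len(n) - 1L) {
    frame <- getFrame(stream, i)
    gray <- .lum(frame@pixels)
    dets <- detect(detector, frame)
    dets <- associateDetections(prevDets, dets, minIou, nextId)
    if (nrow(dets)) nextId <- max(nextId, max(dets$subject_id) + 1L)
    if (nrow(dets)) {
      rows <- lapply(seq_len(nrow(dets)), function(k) {
        b <- as.numeric(dets[k, c("x_min", "y_min", "x_max", "y_max")])
        if (is.null(prevGray))
          return(data.frame(frame_index = i,
                            subject_id = dets$subject_id[k],
                            area = NA_integer_, moved = NA))
        rr <- (b[2] + 1):b[4]; cc <- (b[1] + 1):b[3]
        m <- measureMotion(prevGray[rr, cc, drop = FALSE],
                           gray[rr, cc, drop = FALSE], motion)
        data.frame(frame_index = i, subject_id = dets$subject_id[k],
                   area = m$area, moved = m$moved)
      })
      meas[[i + 1L]] <- do.call(rbind, rows)
    }
    prevGray <- gray
    prevDets <- dets
  }
  measurements <- do.call(rbind, meas)
  if (is.null(measurements))
    measurements <- data.frame(frame_index = integer(),
                               subject_id = integer(),
                               area = integer(), moved = logical())
  ids <- sort(unique(measurements$subject_id))
  states <- lapply(ids, function(id) {
    classifyStates(measurements[measurements$subject_id == id, ,
                                drop = FALSE],
                   state, fps(stream), duration, as.character(id))
  })
  names(states) <- as.character(ids)
  summaries <- lapply(states, summarizeSleep)
  list(summaries = summaries, states = states, measurements = measurements)
}

#' Write / read per-subject sleep summaries as JSON
#'
#' One object per subject: `total_sleep_s`, `total_awake_s`, `unknown_s`,
#' `observed_s`, `bout_count`, `percent_asleep`.
#'
#' @param summaries named list of [SleepSummary-class].
#' @param path JSON file path.
#' @export
writeSummaries <- function(summaries, path) {
  jsonlite::write_json(
    lapply(summaries, function(s) list(
      subject = s@subjectId, total_sleep_s = s@totalSleepS,
      total_awake_s = s@totalAwakeS, unknown_s = s@totalUnknownS,
      observed_s = s@observedS, bout_count = s@boutCount,
      percent_asleep = s@percentAsleep)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSummaries
#' @export
readSummaries <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(s) {
    new("SleepSummary", subjectId = as.character(s$subject),
        totalSleepS = as.numeric(s$total_sleep_s),
        totalAwakeS = as.numeric(s$total_awake_s),
        totalUnknownS = as.numeric(s$unknown_s),
        observedS = as.numeric(s$observed_s),
        boutCount = as.integer(s$bout_count),
        percentAsleep = if (is.null(s$percent_asleep)) NA_real_
                        else as.numeric(s$percent_asleep))
  })
  names(out) <- vapply(out, subjectId, character(1))
  out
}

#' Compare matched sessions from two methods
#'
#' Pairs automated and manual [SleepSummary-class] lists by session id,
#' excludes sessions present on only one side (reporting them), and
#' builds the [comparisonReport()].
#'
#' @param system,manual named lists of [SleepSummary-class], keyed by
#'   session id.
#' @param alpha significance level.
#' @return list with `report` (a [ComparisonReport-class]) and
#'   `excluded` (character session ids dropped for lack of a match).
#' @export
compareSessions <- function(system, manual, alpha = 0.05) {
  common <- intersect(names(system), names(manual))
  excluded <- setdiff(union(names(system), names(manual)), common)
  if (length(common) == 0L) stop("zero overlapping sessions")
  ps <- pairedSessions(common, system[common], manual[common])
  list(report = comparisonReport(ps, alpha), excluded = excluded)
}
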