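#' Read a behavioural-observation event log
#'
#' Parses a continuous focal-sampling event log in the minimal
#' BORIS-export dialect -- a CSV with columns `Time`, `Subject`,
#' `Behavior`, `Status` (names configurable) -- into one
#' [StateSequence-class] per subject, so human observations and the
#' automated pipeline share a single comparison path.  Times are seconds
#' from session start; logs time-stamped on an absolute clock must be
#' normalized beforehand.
#'
#' Every interval between a matched `START`/`STOP` of a sleep label
#' becomes ASLEEP; all other time is AWAKE.  `POINT` events carry no
#' duration and are ignored.  Sequences are discretized at `fps`: frame
#' \eqn{f} is asleep when its start time \eqn{f/\mathrm{fps}} falls inside
#' an interval.
#'
#' @param path CSV file path.
#' @param sessionDuration session length in seconds (> 0).
#' @param fps discretization rate, frames per second.
#' @param sleepLabels character vector of behaviour labels counted as
#'   sleep (case-insensitive).  The default covers sleep scored as a
#'   resting position with eyes closed and/or no perceivable movement.
#' @param subjects optional character vector of subjects that must appear
#'   in the result even without events (all-AWAKE).  When the log has no
#'   events and no subjects are named, a single all-AWAKE sequence for
#'   `"subject"` is returned.
#' @param columns named list mapping the roles `time`, `subject`,
#'   `behavior`, `status` to column names in the file.
#' @return named list of [StateSequence-class], one per subject.
#' @section Errors:
#' A `STOP` without a prior `START` (same subject and label), two `START`s
#' without an intervening `STOP`, and an event time beyond
#' `sessionDuration` are each fatal, reporting the file line number.
#' @export
readObservationLog <- function(path, sessionDuration, fps,
                               sleepLabels = c("sleep", "rest"),
                               subjects = NULL,
                               columns = list(time = "Time",
                                              subject = "Subject",
                                              behavior = "Behavior",
                                              status = "Status")) {
  if (sessionDuration <= 0) stop("sessionDuration must be > 0")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(columns)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("observation log is missing columns: ", paste(miss, collapse = ", "))
  time <- as.numeric(d[[columns$time]])
  subj <- as.character(d[[columns$subject]])
  behav <- tolower(as.character(d[[columns$behavior]]))
  status <- toupper(as.character(d[[columns$status]]))
  sleepLabels <- tolower(sleepLabels)

  open <- list()   # key subject|label -> (start time, line)
  intervals <- list()  # per subject: list of c(start, stop)
  addInterval <- function(s, from, to) {
    intervals[[s]] <<- c(intervals[[s]], list(c(from, to)))
  }
  for (i in seq_along(time)) {
    line <- i + 1L  # header is line 1
    if (is.na(time[i]) || time[i] < 0)
      stop(sprintf("line %d: invalid event time", line))
    if (time[i] > sessionDuration + 1e-6)
      stop(sprintf("line %d: event time %g exceeds session duration %g",
                   line, time[i], sessionDuration))
    if (!behav[i] %in% sleepLabels) next
    key <- paste0(subj[i], "|", behav[i])
    if (status[i] == "START") {
      if (!is.null(open[[key]]))
        stop(sprintf(
          "line %d: START overlaps an open START at line %d (%s/%s)",
          line, open[[key]][2], subj[i], behav[i]))
      open[[key]] <- c(time[i], line)
    } else if (status[i] == "STOP") {
      if (is.null(open[[key]]))
        stop(sprintf("line %d: STOP without prior START (%s/%s)",
                     line, subj[i], behav[i]))
      if (time[i] < open[[key]][1])
        stop(sprintf("line %d: STOP before its START", line))
      addInterval(subj[i], open[[key]][1], time[i])
      open[[key]] <- NULL
    } else if (status[i] != "POINT") {
      stop(sprintf("line %d: unknown status '%s'", line, status[i]))
    }
  }
  for (key in names(open)) {
    s <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    warning(sprintf("unterminated START (%s) closed at session end", key))
    addInterval(s, open[[key]][1], sessionDuration)
  }

  allSubjects <- union(subjects, unique(subj))
  if (length(allSubjects) == 0L) allSubjects <- "subject"
  n <- as.integer(round(sessionDuration * fps))
  out <- lapply(allSubjects, function(s) {
    st <- rep("AWAKE", n)
    for (iv in intervals[[s]]) {
      f0 <- ceiling(iv[1] * fps - 1e-6)
      f1 <- ceiling(iv[2] * fps - 1e-6) - 1
      f0 <- max(f0, 0); f1 <- min(f1, n - 1L)
      if (f1 >= f0) st[(f0 + 1L):(f1 + 1L)] <- "ASLEEP"
    }
    stateSequence(st, fps, s, sessionDuration)
  })
  names(out) <- allSubjects
  out
}

#' Write a state sequence as an observation event log
#'
#' Emits one `START`/`STOP` pair (behaviour `"sleep"`) per sleeping bout,
#' in the same CSV dialect [readObservationLog()] reads, so synthetic
#' observer output can round-trip: reading the written log reproduces the
#' sequence's bouts and total sleep exactly.
#'
#' @param seq a [StateSequence-class] or a named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeObservationLog <- function(seq, path) {
  if (is(seq, "StateSequence")) seq <- stats::setNames(list(seq),
                                                       seq@subjectId)
  rows <- do.call(rbind, lapply(seq, function(s) {
    b <- extractBouts(s)
    if (nrow(b) == 0L) return(NULL)
    data.frame(
      Time = as.vector(rbind(b$start, b$end)),
      Subject = s@subjectId,
      Behavior = "sleep",
      Status = rep(c("START", "STOP"), nrow(b)))
  }))
  if (is.null(rows))
    rows <- data.frame(Time = numeric(), Subject = character(),
                       Behavior = character(), Status = character())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
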