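#' Bounding boxes
#'
#' Boxes use the half-open pixel convention
#' `[x_min, x_max) x [y_min, y_max)` with integer coordinates, origin at
#' the top-left of the frame; the box area is
#' `(x_max - x_min) * (y_max - y_min)` pixels.
#'
#' @param xMin,yMin,xMax,yMax integer pixel coordinates.
#' @return named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
boundingBox <- function(xMin, yMin, xMax, yMax) {
  b <- c(x_min = as.numeric(xMin), y_min = as.numeric(yMin),
         x_max = as.numeric(xMax), y_max = as.numeric(yMax))
  .checkBox(b)
  b
}

.checkBox <- function(b) {
  if (length(b) != 4L || any(is.na(b)))
    stop("a bounding box is four finite numbers (x_min, y_min, x_max, y_max)")
  if (b[[1]] >= b[[3]] || b[[2]] >= b[[4]])
    stop("degenerate bounding box: x_min < x_max and y_min < y_max required")
  invisible(b)
}

#' Clip a box to frame bounds
#'
#' @param box length-4 box vector.
#' @param width,height frame size in pixels.
#' @export
clipBox <- function(box, width, height) {
  b <- c(x_min = max(0, box[[1]]), y_min = max(0, box[[2]]),
         x_max = min(width, box[[3]]), y_max = min(height, box[[4]]))
  .checkBox(b)
  b
}

#' Intersection over union of two boxes
#'
#' Areas are counted as lattice cells under the half-open convention, so
#' identical boxes give exactly 1 and disjoint boxes 0.
#'
#' @param a,b length-4 box vectors (see [boundingBox()]).
#' @return numeric in \[0, 1\].
#' @examples
#' iou(boundingBox(0, 0, 10, 10), boundingBox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  .checkBox(a); .checkBox(b)
  iw <- max(0, min(a[[3]], b[[3]]) - max(a[[1]], b[[1]]))
  ih <- max(0, min(a[[4]], b[[4]]) - max(a[[2]], b[[2]]))
  inter <- iw * ih
  areaA <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]])
  areaB <- (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])
  inter / (areaA + areaB - inter)
}

.emptyDetections <- function() {
  data.frame(frame_index = integer(), subject_id = integer(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric())
}

#' Associate detections across frames
#'
#' Greedy matching in descending IoU order: each current detection is
#' matched to the unclaimed previous detection of highest overlap, pairs
#' below `minIou` are left unmatched, and unmatched current detections
#' receive fresh subject ids.  Kennelled dogs move slowly relative to the
#' frame rate, so greedy matching at a modest threshold suffices in place
#' of optimal assignment.  A subject id is never assigned to two
#' detections in the same frame.
#'
#' @param prev detection data frame for the previous frame; `subject_id`
#'   must be filled.
#' @param cur detection data frame for the current frame.
#' @param minIou minimum IoU for a match (default 0.3).
#' @param nextId first id to use for unmatched detections; defaults to one
#'   more than the largest id seen in `prev`.
#' @return `cur` with `subject_id` assigned.
#' @export
associateDetections <- function(prev, cur, minIou = 0.3, nextId = NULL) {
  if (nrow(cur) == 0L) return(cur)
  cur$subject_id <- NA_integer_
  if (is.null(nextId))
    nextId <- if (nrow(prev)) max(prev$subject_id) + 1L else 1L
  if (nrow(prev)) {
    pairs <- expand.grid(p = seq_len(nrow(prev)), c = seq_len(nrow(cur)))
    pairs$iou <- mapply(function(p, c)
      iou(as.numeric(prev[p, c("x_min", "y_min", "x_max", "y_max")]),
          as.numeric(cur[c, c("x_min", "y_min", "x_max", "y_max")])),
      pairs$p, pairs$c)
    pairs <- pairs[order(-pairs$iou, pairs$p, pairs$c), , drop = FALSE]
    usedP <- logical(nrow(prev)); usedC <- logical(nrow(cur))
    for (k in seq_len(nrow(pairs))) {
      if (pairs$iou[k] < minIou) break
      p <- pairs$p[k]; c <- pairs$c[k]
      if (usedP[p] || usedC[c]) next
      cur$subject_id[c] <- prev$subject_id[p]
      usedP[p] <- TRUE; usedC[c] <- TRUE
    }
  }
  for (c in which(is.na(cur$subject_id))) {
    cur$subject_id[c] <- as.integer(nextId)
    nextId <- nextId + 1L
  }
  cur
}

#' @describeIn detect replays true boxes recorded by the synthetic
#'   generator; confidence is 1.  Requesting a frame index the ground
#'   truth does not cover is an error; a covered frame with no dogs yields
#'   zero rows.
setMethod("detect", "GroundTruthDetector", function(object, frame) {
  i <- frame@index
  if (i < 0L || i >= object@nframes)
    stop(sprintf("ground truth has no frame %d (covers [0, %d))",
                 i, object@nframes))
  d <- object@detections[object@detections$frame_index == i, , drop = FALSE]
  rownames(d) <- NULL
  d$subject_id <- rep(NA_integer_, nrow(d))  # ids are assigned by tracking
  d
})

#' @describeIn detect returns one configured fixed box per frame
#'   (confidence 1), for footage of a single kennel where the resting area
#'   is a known region of interest.
setMethod("detect", "StaticRoiDetector", function(object, frame) {
  d <- dim(frame@pixels)
  b <- clipBox(object@box, d[2], d[1])
  data.frame(frame_index = frame@index, subject_id = NA_integer_,
             x_min = b[[1]], y_min = b[[2]], x_max = b[[3]], y_max = b[[4]],
             confidence = 1)
})

#' Construct the bundled detectors
#'
#' @param detections detection data frame (or path to a detection CSV)
#'   holding true boxes.
#' @param nframes number of frames the ground truth covers.
#' @return a [Detector-class].
#' @export
groundTruthDetector <- function(detections, nframes) {
  if (is.character(detections)) detections <- readDetections(detections)
  new("GroundTruthDetector", detections = detections,
      nframes = as.integer(nframes))
}

#' @rdname groundTruthDetector
#' @param box fixed region of interest, length-4 box vector.
#' @export
staticRoiDetector <- function(box) {
  .checkBox(box)
  new("StaticRoiDetector", box = as.numeric(box))
}

#' Detection CSV interchange
#'
#' Detections travel as CSV with columns `frame_index`, `subject_id`,
#' `x_min`, `y_min`, `x_max`, `y_max`, `confidence`, so external detectors
#' can feed the pipeline.
#'
#' @param path CSV file path.
#' @export
readDetections <- function(path) {
  d <- utils::read.csv(path)
  need <- names(.emptyDetections())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("detection CSV is missing columns: ", paste(miss, collapse = ", "))
  d[need]
}

#' @rdname readDetections
#' @param detections detection data frame.
#' @export
writeDetections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
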