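#' Construct a Frame
#'
#' @param pixels matrix or h x w x 3 array of intensities in \[0, 255\].
#' @param index 0-based frame index.
#' @param timestamp seconds from session start; defaults to `index / fps`
#'   when `fps` is given.
#' @param mode `"DAY_COLOUR"` or `"NIGHT_GRAY"`; inferred from the channel
#'   count when missing.
#' @param fps optional frame rate used to derive the timestamp.
#' @return a [Frame-class].
#' @export
newFrame <- function(pixels, index, timestamp = NULL, mode = NULL,
                     fps = NULL) {
  if (is.null(mode))
    mode <- if (length(dim(pixels)) == 3L) "DAY_COLOUR" else "NIGHT_GRAY"
  if (is.null(timestamp)) {
    if (is.null(fps)) stop("either timestamp or fps is required")
    timestamp <- index / fps
  }
  new("Frame", pixels = as.array(pixels), index = as.integer(index),
      timestamp = as.numeric(timestamp), mode = mode)
}

#' Open a directory of numbered frames as a stream
#'
#' Reads a directory of PNG frame files, named so that lexicographic order
#' is frame order (e.g. `frame_000001.png`), into a
#' [DirectoryFrameStream-class].  Timing is derived from the frame index:
#' frame \eqn{i} has timestamp \eqn{i / \mathrm{fps}}.  Consumer-CCTV
#' recorders rarely embed trustworthy timing metadata and the frame rate of
#' such footage must be known to the analyst, so `fpsOverride` is mandatory
#' for directory sources.  Video containers (MP4/AVI) are not decoded;
#' export the footage to numbered frames first.
#'
#' @param path directory containing the frame images.
#' @param fpsOverride frames per second of the recording (required).
#' @return a [DirectoryFrameStream-class].
#' @details All frames must share one shape; a frame whose dimensions
#'   disagree with frame 0 is a fatal error at read time, naming the
#'   offending frame.
#' @examples
#' d <- tempfile(); dir.create(d)
#' for (i in 1:3)
#'   png::writePNG(matrix(runif(64), 8, 8), file.path(d, sprintf("f%03d.png", i)))
#' s <- openFrameSource(d, fpsOverride = 5)
#' nframes(s)
#' getFrame(s, 2)@timestamp  # 0.4 s
#' @export
openFrameSource <- function(path, fpsOverride = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (!dir.exists(path))
    stop("not a directory (video containers are not decoded; ",
         "export frames first): ", path)
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frames in ", path)
  if (is.null(fpsOverride))
    stop("fpsOverride is required for directory sources")
  first <- .readPixels(files[1L])
  new("DirectoryFrameStream", path = path, files = files,
      fps = as.numeric(fpsOverride), nframes = length(files),
      dim = as.integer(dim(first)[1:2]))
}

#' @describeIn getFrame read a PNG frame from disk, checking its shape
setMethod("getFrame", "DirectoryFrameStream", function(x, index) {
  .checkFrameIndex(index, x@nframes)
  px <- .readPixels(x@files[index + 1L])
  d <- dim(px)
  if (d[1] != x@dim[1] || d[2] != x@dim[2])
    stop(sprintf(
      "frame %d ('%s') is %dx%d, expected %dx%d", index,
      basename(x@files[index + 1L]), d[1], d[2], x@dim[1], x@dim[2]))
  newFrame(px, index, index / x@fps)
})

# Read a PNG into 0..255 integers; alpha channels are dropped.
.readPixels <- function(file) {
  px <- png::readPNG(file)
  d <- dim(px)
  if (length(d) == 3L) {
    if (d[3] == 2L) px <- px[, , 1L]            # gray + alpha
    else if (d[3] == 4L) px <- px[, , 1:3]       # RGBA
    else if (d[3] != 3L) stop("unsupported channel count: ", d[3])
  }
  round(px * 255)
}

#' Convert a frame to grayscale
#'
#' Colour frames are converted to 8-bit luminance with the ITU-R BT.601
#' weights, `round(0.299 R + 0.587 G + 0.114 B)` clipped to \[0, 255\];
#' grayscale frames pass through unchanged, so the operation is idempotent.
#'
#' @param frame a [Frame-class], or a raw pixel matrix / h x w x 3 array.
#' @return an object of the same kind as the input, single-channel.
#' @examples
#' toGrayscale(array(c(255, 0, 0), c(1, 1, 3)))  # 76
#' @export
toGrayscale <- function(frame) {
  if (is(frame, "Frame")) {
    px <- .lum(frame@pixels)
    return(new("Frame", pixels = px, index = frame@index,
               timestamp = frame@timestamp, mode = frame@mode))
  }
  .lum(frame)
}

.lum <- function(px) {
  d <- dim(px)
  if (length(d) == 2L) return(px)
  if (length(d) != 3L || !d[3] %in% c(1L, 3L))
    stop("frame must have 1 or 3 channels")
  if (d[3] == 1L) return(matrix(px, d[1], d[2]))
  g <- round(0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L])
  pmin(pmax(g, 0), 255)
}

#' Write a stream of frames to a directory
#'
#' Inverse of [openFrameSource()]: writes each frame as
#' `frame_%06d.png`.  Used by the synthetic renderer.
#'
#' @param stream a [FrameStream-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFrames <- function(stream, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nframes(stream)) - 1L) {
    fr <- getFrame(stream, i)
    png::writePNG(fr@pixels / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}
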