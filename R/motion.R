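#' Motion-detector parameters
#'
#' Defaults follow the classical frame-differencing recipe: a heavy
#' Gaussian blur to suppress sensor noise and compression artefacts, a
#' conservative delta threshold of 25 intensity units, a small dilation to
#' fuse fragmented motion pixels, and a minimum component area that
#' discards isolated specks.  All are configuration choices of this
#' package and can be overridden per run (`motion:` block of a YAML
#' config).
#'
#' @param blurKernel odd integer >= 1 (default 21).
#' @param deltaThreshold integer in \[1, 255\] (default 25).
#' @param dilateKernel odd integer >= 1 (default 3).
#' @param dilateIterations integer >= 0 (default 2).
#' @param minComponentArea integer >= 1 pixels (default 25).
#' @param minMotionFraction numeric >= 0, qualifying area as a fraction of
#'   the crop area required to flag movement (default 0.005).
#' @return a [MotionParams-class].
#' @export
motionParams <- function(blurKernel = 21, deltaThreshold = 25,
                         dilateKernel = 3, dilateIterations = 2,
                         minComponentArea = 25, minMotionFraction = 0.005) {
  new("MotionParams",
      blurKernel = as.integer(blurKernel),
      deltaThreshold = as.integer(deltaThreshold),
      dilateKernel = as.integer(dilateKernel),
      dilateIterations = as.integer(dilateIterations),
      minComponentArea = as.integer(minComponentArea),
      minMotionFraction = as.numeric(minMotionFraction))
}

# Reflect an out-of-range index into [1, n] (edge pixel duplicated).
.reflectIdx <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# 1-d convolution along rows with reflect border, vectorized over columns.
.convRows <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in -r:r)
    out <- out + w[j + r + 1L] * m[.reflectIdx(seq_len(n) + j, n), ,
                                   drop = FALSE]
  out
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with the conventional 8-bit video kernel:
#' sigma is derived from the kernel width as
#' `0.3 * ((kernel - 1) / 2 - 1) + 0.8`, weights are the sampled Gaussian
#' normalized to sum 1, borders are handled by reflection (edge pixel
#' duplicated), and the result is rounded back to integer intensities.
#' `kernel = 1` is the identity.
#'
#' @param img numeric matrix of intensities.
#' @param kernel odd integer >= 1.
#' @return blurred matrix, same shape.
#' @export
blurImage <- function(img, kernel) {
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("blur kernel must be an odd integer >= 1")
  if (kernel == 1L) return(img)
  w <- gaussianKernel(kernel)
  round(t(.convRows(t(.convRows(img, w)), w)))
}

#' @rdname blurImage
#' @return `gaussianKernel` returns the normalized 1-d weight vector.
#' @export
gaussianKernel <- function(kernel) {
  sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  c0 <- (kernel - 1) / 2
  w <- exp(-((seq_len(kernel) - 1 - c0)^2) / (2 * sigma^2))
  w / sum(w)
}

#' Absolute difference of consecutive frames
#'
#' @param prev,cur equal-shaped grayscale matrices.
#' @return matrix of per-pixel `|cur - prev|`.
#' @export
frameDelta <- function(prev, cur) {
  if (!identical(dim(prev), dim(cur)))
    stop(sprintf("frame shapes differ: %s vs %s",
                 paste(dim(prev), collapse = "x"),
                 paste(dim(cur), collapse = "x")))
  abs(cur - prev)
}

#' Binarize a delta image
#'
#' A pixel is foreground iff its value is strictly greater than the
#' threshold.
#'
#' @param delta numeric matrix.
#' @param threshold integer in \[1, 255\].
#' @return 0/1 integer matrix.
#' @export
binarizeImage <- function(delta, threshold) {
  threshold <- as.numeric(threshold)
  if (is.na(threshold) || threshold < 1 || threshold > 255)
    stop("threshold must lie in [1, 255]")
  m <- (delta > threshold) + 0L
  dim(m) <- dim(delta)
  m
}

# Shift a matrix by (di, dj), filling vacated cells with `fill`.
.shiftMat <- function(m, di, dj, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  ri <- max(1L, 1L + di):min(n, n + di)
  rj <- max(1L, 1L + dj):min(p, p + dj)
  if (length(ri) > 0L && length(rj) > 0L)
    out[ri, rj] <- m[ri - di, rj - dj, drop = FALSE]
  out
}

#' Morphological dilation of a binary image
#'
#' Dilation with a square structuring element of width `kernel`, applied
#' `iterations` times; the element is truncated at the image border.
#' Zero iterations is the identity.
#'
#' @param binary 0/1 matrix.
#' @param kernel odd integer >= 1.
#' @param iterations integer >= 0.
#' @return 0/1 integer matrix.
#' @export
dilateBinary <- function(binary, kernel = 3, iterations = 1) {
  kernel <- as.integer(kernel); iterations <- as.integer(iterations)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("dilate kernel must be an odd integer >= 1")
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0")
  r <- (kernel - 1L) %/% 2L
  out <- (binary > 0) + 0L
  if (r == 0L) return(out)
  for (it in seq_len(iterations)) {
    acc <- out
    for (di in -r:r) for (dj in -r:r)
      if (di != 0L || dj != 0L)
        acc <- pmax(acc, .shiftMat(out, di, dj))
    out <- acc
  }
  out
}

#' Areas of 8-connected foreground components
#'
#' Labels foreground pixels by minimum-index label propagation over the
#' 8-neighbourhood (diagonally touching pixels belong to one component)
#' and returns the component pixel counts in descending order.
#'
#' @param binary 0/1 matrix.
#' @return integer vector of areas, largest first; empty for an empty
#'   image.
#' @export
componentAreas <- function(binary) {
  fg <- binary > 0
  if (!any(fg)) return(integer())
  n <- nrow(binary); p <- ncol(binary)
  lab <- matrix(Inf, n, p)
  lab[fg] <- which(fg)
  repeat {
    nl <- lab
    for (di in -1:1) for (dj in -1:1)
      if (di != 0L || dj != 0L)
        nl <- pmin(nl, .shiftMat(lab, di, dj, fill = Inf))
    nl[!fg] <- Inf
    nl <- pmin(nl, lab)
    if (identical(nl, lab)) break
    lab <- nl
  }
  areas <- as.integer(table(lab[fg]))
  sort(areas, decreasing = TRUE)
}

#' Measure movement between two crops of one subject
#'
#' Composes the six movement-detection steps on the bounding-box content
#' of consecutive frames: grayscale conversion, Gaussian blur of each
#' crop, inter-frame absolute delta, binarization, dilation, and
#' 8-connected component areas.  The qualifying area is the total area of
#' components of at least `minComponentArea` pixels (limb movement and
#' whole-body movement both count), and the subject is flagged as moved
#' when the qualifying area reaches `minMotionFraction` of the crop area.
#'
#' Both crops should be taken at the *current* frame's box so that slow
#' drift of the detector's box is not itself counted as motion.
#'
#' @param prevCrop,curCrop equal-shaped crops (grayscale matrices or
#'   colour arrays) of the same subject's box in consecutive frames.
#' @param params a [MotionParams-class].
#' @return list with elements `area` (qualifying pixels), `moved`
#'   (logical), and `componentAreas` (all component areas, descending).
#' @export
measureMotion <- function(prevCrop, curCrop, params = motionParams()) {
  g1 <- .lum(prevCrop)
  g2 <- .lum(curCrop)
  if (!identical(dim(g1), dim(g2)))
    stop("crops must have equal shapes")
  b1 <- blurImage(g1, params@blurKernel)
  b2 <- blurImage(g2, params@blurKernel)
  delta <- frameDelta(b1, b2)
  bin <- binarizeImage(delta, params@deltaThreshold)
  dil <- dilateBinary(bin, params@dilateKernel, params@dilateIterations)
  areas <- componentAreas(dil)
  qualifying <- sum(areas[areas >= params@minComponentArea])
  boxArea <- prod(dim(g1))
  list(area = as.integer(qualifying),
       moved = qualifying >= params@minMotionFraction * boxArea,
       componentAreas = areas)
}
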