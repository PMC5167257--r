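#' Maximum-intensity projection of a stack
#'
#' Element-wise maximum over all frames; used as the still image on which a
#' line of interest is placed.
#'
#' @param stack a [KymoStack-class].
#' @return a numeric matrix with the stack's frame shape.
#' @export
maxIntensityProjection <- function(stack) {
  Reduce(pmax, frameData(stack))
}

# Integer 8-connected line rasterization between two pixel centers,
# both endpoints included.
bresenhamLine <- function(x0, y0, x1, y1) {
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- max(dx, dy) + 1L
  out <- matrix(0L, n, 2L)
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Rasterize a line of interest
#'
#' Converts the polyline into an ordered list of integer sample centers (the
#' 8-connected Bresenham rasterization of each segment, concatenated without
#' duplicating shared vertices). For width w > 1, each center carries w
#' sample pixels placed symmetrically along the direction perpendicular to
#' the local segment, rounded to integer pixels; at polyline joints the later
#' segment's perpendicular is used. Offset samples falling outside the image
#' are dropped (the width average then runs over fewer pixels rather than
#' zero-padding, which would darken edges).
#'
#' @param loi a [LineOfInterest-class].
#' @param imageShape integer vector \code{c(nrow, ncol)} of the frames.
#' @return list with \code{centers} (L x 2 matrix of x, y) and
#'   \code{offsets} (list of L matrices of the in-bounds sample pixels).
#' @export
rasterizeLOI <- function(loi, imageShape) {
  v <- loiVertices(loi)
  w <- loiWidth(loi)
  nr <- imageShape[1L]; nc <- imageShape[2L]
  if (any(v[, 1] < 1 | v[, 1] > nc | v[, 2] < 1 | v[, 2] > nr))
    stop("LOI vertices must lie inside the image (1..ncol, 1..nrow)")
  centers <- NULL
  segIdx <- integer()
  for (s in seq_len(nrow(v) - 1L)) {
    pts <- bresenhamLine(v[s, 1], v[s, 2], v[s + 1, 1], v[s + 1, 2])
    if (s > 1L) pts <- pts[-1L, , drop = FALSE]  # shared vertex appears once
    centers <- rbind(centers, pts)
    segIdx <- c(segIdx, rep.int(s, nrow(pts)))
  }
  half <- (w - 1L) %/% 2L
  offsets <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    s <- segIdx[i]
    d <- c(v[s + 1, 1] - v[s, 1], v[s + 1, 2] - v[s, 2])
    perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
    off <- seq.int(-half, half)
    samp <- cbind(centers[i, 1] + round(off * perp[1]),
                  centers[i, 2] + round(off * perp[2]))
    keep <- samp[, 1] >= 1 & samp[, 1] <= nc & samp[, 2] >= 1 & samp[, 2] <= nr
    samp <- samp[keep, , drop = FALSE]
    colnames(samp) <- c("x", "y")
    offsets[[i]] <- samp
  }
  list(centers = centers, offsets = offsets)
}

#' Build a kymograph
#'
#' Samples the stack along the rasterized line of interest at each selected
#' frame. Cell \code{[t, j]} is the arithmetic mean intensity over the width
#' samples of center j in frame t; rows are ordered by frame index and
#' column 1 corresponds to the start of the line (the origin).
#'
#' @param stack a [KymoStack-class].
#' @param loi a [LineOfInterest-class].
#' @param frames integer vector of 1-based frame indices (default: all).
#' @return a [Kymograph-class].
#' @export
buildKymograph <- function(stack, loi, frames = seq_len(nFrames(stack))) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nFrames(stack)))
    stop("frame indices out of range")
  if (length(frames) < 2L)
    stop("kymograph needs at least 2 frames; got ", length(frames))
  shape <- dim(frameData(stack)[[1L]])
  ras <- rasterizeLOI(loi, shape)
  L <- nrow(ras$centers)
  # linear indices per center (matrix index = (row=y, col=x))
  lin <- lapply(ras$offsets, function(s) (s[, 1] - 1L) * shape[1L] + s[, 2])
  vals <- matrix(0, length(frames), L)
  for (ti in seq_along(frames)) {
    f <- frameData(stack)[[frames[ti]]]
    vals[ti, ] <- vapply(lin, function(ix) mean(f[ix]), numeric(1))
  }
  new("Kymograph", values = vals, frameIndices = frames,
      sampleCoords = ras$centers, sampleOffsets = ras$offsets,
      pxSize = pixelSize(stack), dt = frameInterval(stack),
      bitDepth = bitDepth(stack),
      distanceUnit = stack@distanceUnit, timeUnit = stack@timeUnit)
}

#' Save a kymograph for inspection
#'
#' Writes the kymograph matrix as a tab-delimited text file (rows = frames)
#' and, optionally, as a single-page TIFF at the source bit depth.
#'
#' @param kymo a [Kymograph-class].
#' @param txtPath path for the tab-delimited matrix (NULL to skip).
#' @param tifPath path for the single-page TIFF (NULL to skip).
#' @return invisibly, the paths written.
#' @export
saveKymograph <- function(kymo, txtPath = NULL, tifPath = NULL) {
  if (!is.null(txtPath))
    utils::write.table(kymoValues(kymo), txtPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(tifPath)) {
    maxv <- 2^bitDepth(kymo) - 1
    tiff::writeTIFF(pmin(pmax(round(kymoValues(kymo)), 0), maxv) / maxv,
                    tifPath, bits.per.sample = as.integer(bitDepth(kymo)),
                    compression = "none")
  }
  invisible(c(txtPath, tifPath))
}
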