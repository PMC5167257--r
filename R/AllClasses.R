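#' @import methods
NULL

#' KymoStack: a fluorescence image time-series
#'
#' Container for an ordered set of 2-D intensity frames sharing one shape and
#' bit depth, together with the physical calibration (distance per pixel,
#' time per frame) needed to convert pixel/frame statistics into user units.
#'
#' @slot frames list of numeric matrices, one per time point, identical
#'   dimensions, values in \code{[0, 2^bitDepth - 1]}.
#' @slot bitDepth integer, 8 or 16.
#' @slot pxSize positive numeric, physical distance per pixel.
#' @slot dt positive numeric, physical time per frame.
#' @slot distanceUnit,timeUnit unit labels carried through to output files.
#'
#' @seealso [readStack()], [generateBeadStack()], [buildKymograph()]
#' @export
setClass("KymoStack",
  representation(
    frames = "list",
    bitDepth = "integer",
    pxSize = "numeric",
    dt = "numeric",
    distanceUnit = "character",
    timeUnit = "character"
  ),
  prototype(
    bitDepth = 8L, pxSize = 1, dt = 1,
    distanceUnit = "px", timeUnit = "frame"
  )
)

setValidity("KymoStack", function(object) {
  msg <- character()
  if (length(object@frames) < 1L) msg <- c(msg, "stack must contain at least one frame")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    msg <- c(msg, "all frames must be matrices")
  if (length(object@frames) >= 1L) {
    d0 <- dim(object@frames[[1L]])
    same <- vapply(object@frames, function(f) identical(dim(f), d0), logical(1))
    if (!all(same)) msg <- c(msg, "all frames must share one shape")
  }
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  rng <- range(vapply(object@frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > 2^object@bitDepth - 1)
    msg <- c(msg, sprintf("intensities must lie in [0, %d]", 2^object@bitDepth - 1))
  if (!(length(object@pxSize) == 1L && object@pxSize > 0)) msg <- c(msg, "pxSize must be a single positive number")
  if (!(length(object@dt) == 1L && object@dt > 0)) msg <- c(msg, "dt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a KymoStack
#'
#' @param frames list of numeric matrices (one per frame, identical shape).
#' @param bitDepth image bit depth (8 or 16).
#' @param pxSize physical distance per pixel (> 0).
#' @param dt physical time per frame (> 0).
#' @param distanceUnit,timeUnit unit labels (defaults "px", "frame").
#' @return a [KymoStack-class] object.
#' @export
KymoStack <- function(frames, bitDepth = 8L, pxSize = 1, dt = 1,
                      distanceUnit = "px", timeUnit = "frame") {
  new("KymoStack", frames = frames, bitDepth = as.integer(bitDepth),
      pxSize = pxSize, dt = dt,
      distanceUnit = distanceUnit, timeUnit = timeUnit)
}

#' LineOfInterest: sampling polyline for kymograph construction
#'
#' An ordered polyline in image pixel coordinates (1-based, x = column,
#' y = row) along which the kymograph is sampled, plus a sampling width.
#' Width 3 or 5 averages pixels placed perpendicular to the local segment,
#' compensating for small drift of the tracked object orthogonal to the line.
#'
#' @slot vertices numeric matrix with columns \code{x}, \code{y}; at least
#'   two rows, consecutive vertices distinct.
#' @slot width integer, one of 1, 3, 5.
#' @export
setClass("LineOfInterest",
  representation(vertices = "matrix", width = "integer"),
  prototype(width = 1L)
)

setValidity("LineOfInterest", function(object) {
  msg <- character()
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) msg <- c(msg, "vertices must be a numeric 2-column matrix (x, y)")
  else {
    if (nrow(v) < 2L) msg <- c(msg, "need at least two vertices")
    else {
      dup <- rowSums(abs(diff(v))) == 0
      if (any(dup)) msg <- c(msg, "consecutive vertices must be distinct")
    }
  }
  if (!object@width %in% c(1L, 3L, 5L)) msg <- c(msg, "width must be 1, 3 or 5")
  if (length(msg)) msg else TRUE
})

#' Construct a LineOfInterest
#'
#' @param vertices 2-column numeric matrix of (x, y) pixel coordinates
#'   (1-based), or a vector \code{c(x1, y1, x2, y2, ...)}.
#' @param width sampling width in pixels: 1, 3 or 5.
#' @return a [LineOfInterest-class] object.
#' @export
LineOfInterest <- function(vertices, width = 1L) {
  if (is.vector(vertices)) vertices <- matrix(vertices, ncol = 2L, byrow = TRUE)
  colnames(vertices) <- c("x", "y")
  new("LineOfInterest", vertices = vertices, width = as.integer(width))
}

#' Kymograph: space-time intensity matrix
#'
#' Rows are time frames (in the order of the selected frames), columns are
#' positions along the line of interest; column 1 corresponds to the start of
#' the line (the origin). Motion of an object along the line appears as a
#' sloped contour.
#'
#' @slot values T x L numeric matrix of (width-averaged) intensities.
#' @slot frameIndices the T source frame numbers (1-based, original stack).
#' @slot sampleCoords L x 2 matrix of (x, y) centers along the rasterized line.
#' @slot sampleOffsets list of L integer matrices, the width-sample pixel
#'   coordinates actually averaged for each center (after clipping).
#' @slot pxSize,dt,bitDepth,distanceUnit,timeUnit calibration copied from the
#'   source stack.
#' @export
setClass("Kymograph",
  representation(
    values = "matrix",
    frameIndices = "integer",
    sampleCoords = "matrix",
    sampleOffsets = "list",
    pxSize = "numeric",
    dt = "numeric",
    bitDepth = "integer",
    distanceUnit = "character",
    timeUnit = "character"
  )
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@frameIndices))
    msg <- c(msg, "one row per selected frame required")
  if (ncol(object@values) != nrow(object@sampleCoords))
    msg <- c(msg, "one column per line sample required")
  if (any(object@values < 0)) msg <- c(msg, "kymograph values must be non-negative")
  if (is.unsorted(object@frameIndices, strictly = TRUE))
    msg <- c(msg, "frameIndices must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' TrackSet: linked peak trajectories on a kymograph
#'
#' Stores track nodes in long form: one row per (track, frame) node with the
#' kymograph row, original frame number, column position (pixels along the
#' line), raw intensity, and the detection kind that was tracked. Branch
#' events (splits/merges) and the run parameters are carried alongside.
#'
#' @slot nodes data.frame with columns \code{track}, \code{row}, \code{frame},
#'   \code{column}, \code{intensity}, \code{kind}; frames strictly increasing
#'   within a track.
#' @slot branches data.frame of branch events (possibly empty) with columns
#'   \code{track}, \code{parent}, \code{column}, \code{frame},
#'   \code{direction}.
#' @slot params list of the linking/pruning parameters used.
#' @export
setClass("TrackSet",
  representation(nodes = "data.frame", branches = "data.frame", params = "list"),
  prototype(
    nodes = data.frame(track = integer(), row = integer(), frame = integer(),
                       column = numeric(), intensity = numeric(),
                       kind = character(), stringsAsFactors = FALSE),
    branches = data.frame(track = integer(), parent = integer(),
                          column = numeric(), frame = integer(),
                          direction = character(), stringsAsFactors = FALSE),
    params = list()
  )
)

setValidity("TrackSet", function(object) {
  msg <- character()
  need <- c("track", "row", "frame", "column", "intensity", "kind")
  if (!all(need %in% names(object@nodes)))
    msg <- c(msg, paste("nodes must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@nodes)) {
    ok <- vapply(split(object@nodes$frame, object@nodes$track),
                 function(f) !is.unsorted(f, strictly = TRUE), logical(1))
    if (!all(ok)) msg <- c(msg, "frames must be strictly increasing within each track")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: simulated bead time-series with ground truth
#'
#' A simulated fluorescence stack of point-source beads (convolved with a
#' 5x5 disk filter and a 3x3 averaging filter) plus the unrounded true bead
#' positions per frame, for accuracy evaluation of the tracking pipeline.
#'
#' @slot stack the rendered [KymoStack-class].
#' @slot truth data.frame with columns \code{frame}, \code{bead}, \code{x}
#'   (true position, pixels, possibly fractional), \code{clipped} (logical,
#'   TRUE where the walk hit the image border and was clipped).
#' @slot params list of generator parameters (nBeads, spacing, nFrames,
#'   imageSize, beadRow, walkSd, noiseSd, seed).
#' @export
setClass("SyntheticScene",
  representation(stack = "KymoStack", truth = "data.frame", params = "list")
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  need <- c("frame", "bead", "x", "clipped")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must have columns:", paste(need, collapse = ", ")))
  else {
    nb <- length(unique(object@truth$bead))
    nf <- length(object@stack@frames)
    if (nrow(object@truth) != nb * nf)
      msg <- c(msg, "truth must have one entry per bead per frame")
  }
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "KymoStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("KymoStack: %d frame(s) of %d x %d, %d-bit\n",
              length(object@frames), d[1], d[2], object@bitDepth))
  cat(sprintf("  calibration: %g %s/px, %g %s/frame\n",
              object@pxSize, object@distanceUnit, object@dt, object@timeUnit))
})

setMethod("show", "LineOfInterest", function(object) {
  cat(sprintf("LineOfInterest: %d vertices, width %d px\n",
              nrow(object@vertices), object@width))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d frames x %d positions (%d-bit source)\n",
              nrow(object@values), ncol(object@values), object@bitDepth))
  cat(sprintf("  frames %d..%d; calibration %g %s/px, %g %s/frame\n",
              min(object@frameIndices), max(object@frameIndices),
              object@pxSize, object@distanceUnit, object@dt, object@timeUnit))
})

setMethod("show", "TrackSet", function(object) {
  nt <- length(unique(object@nodes$track))
  cat(sprintf("TrackSet: %d track(s), %d node(s), %d branch event(s)\n",
              nt, nrow(object@nodes), nrow(object@branches)))
})

setMethod("show", "SyntheticScene", function(object) {
  p <- object@params
  cat(sprintf("SyntheticScene: %d bead(s), %d frame(s), walk s.d. %g px/frame, noise s.d. %g\n",
              p$nBeads, p$nFrames, p$walkSd, p$noiseSd))
})
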