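#' Detect and track peaks on a kymograph
#'
#' Runs the detection/tracking chain on a built kymograph: row-wise Otsu
#' segmentation, peak or edge detection per \code{params$peakMethod},
#' distance-minimization linking (search radius lambda1), short-track
#' removal (minimum length lambda2), optional redundant-track removal, and
#' optional branch (split/merge) detection in the omega1/omega2 windows.
#'
#' @param kymo a [Kymograph-class].
#' @param params a [KymoParams()] list.
#' @return a [TrackSet-class] with original frame numbers on its nodes.
#' @export
trackKymograph <- function(kymo, params = KymoParams()) {
  mask <- segmentRows(kymo)
  peaks <- switch(params$peakMethod,
    findpeaks = detectPeaks(kymo, mask, "findpeaks", subpixel = params$subpixel),
    watershed = detectPeaks(kymo, mask, "watershed",
                            saddleMin = params$saddleMin,
                            subpixel = params$subpixel),
    canny = detectEdges(kymo, mask, sigma = params$cannySigma,
                        low = params$cannyLow, high = params$cannyHigh),
    stop("unknown peak method: ", params$peakMethod)
  )
  tracks <- linkPeaks(peaks, lambda1 = params$lambda1,
                      gapTolerance = params$gapTolerance,
                      nRows = nrow(kymoValues(kymo)))
  tracks <- filterShortTracks(tracks, params$lambda2)
  if (isTRUE(params$removeRedundant)) tracks <- removeRedundant(tracks)
  tracks <- assignFrames(tracks, kymo)
  if (isTRUE(params$linkBranches))
    tracks <- detectBranchEvents(tracks, params$omega1, params$omega2)
  p <- params
  tracks@params <- unclass(p)
  tracks
}

#' Full kymograph analysis of a TIFF time-series
#'
#' The end-to-end pipeline: read (or accept) an image stack, select frames,
#' build the kymograph along the line of interest, track it, and write the
#' six tab-delimited output files.
#'
#' @param stack a [KymoStack-class], or a path to a multi-page TIFF.
#' @param loi a [LineOfInterest-class], or a path to an LOI coordinate
#'   file (see [readLOI()]); the width in \code{params$loiWidth} is applied.
#' @param params a [KymoParams()] list.
#' @param outDir output directory (NULL to skip writing).
#' @param loiIndex subfolder number for the outputs (default 1).
#' @param pxSize,dt,distanceUnit,timeUnit calibration, used when
#'   \code{stack} is a file path.
#' @return list with \code{stack}, \code{loi}, \code{kymo}, \code{tracks},
#'   \code{outDir} (the subfolder written, or NULL).
#' @export
runKymography <- function(stack, loi, params = KymoParams(), outDir = NULL,
                          loiIndex = 1L, pxSize = 1, dt = 1,
                          distanceUnit = "px", timeUnit = "frame") {
  inputs <- character()
  if (is.character(stack)) {
    inputs <- c(inputs, input_tif = stack)
    stack <- readStack(stack, pxSize = pxSize, dt = dt,
                       distanceUnit = distanceUnit, timeUnit = timeUnit)
  }
  if (is.character(loi)) {
    inputs <- c(inputs, loi_file = loi)
    loi <- readLOI(loi, width = params$loiWidth)
  }
  frames <- parseFrameSpec(params$frameSpec, nFrames(stack))
  kymo <- buildKymograph(stack, loi, frames)
  tracks <- trackKymograph(kymo, params)
  sub <- NULL
  if (!is.null(outDir))
    sub <- writeOutputs(tracks, kymo, loi, params, outDir,
                        loiIndex = loiIndex, inputs = inputs)
  list(stack = stack, loi = loi, kymo = kymo, tracks = tracks, outDir = sub)
}
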