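#' Read a multi-page TIFF time-series
#'
#' Reads an uncompressed, grayscale, multi-page TIFF into a [KymoStack-class],
#' one frame per page in page order. Intensities are kept unscaled at the
#' file's bit depth (8 or 16). Compressed files are rejected rather than
#' silently decoded, mirroring the stated input contract of the analysis.
#'
#' @param path path to a multi-page TIFF file.
#' @param pxSize,dt physical calibration: distance per pixel and time per
#'   frame (both > 0, default 1).
#' @param distanceUnit,timeUnit unit labels (defaults "px", "frame").
#' @return a [KymoStack-class]; a single-page file yields a valid 1-frame
#'   stack (kymograph construction will later refuse it with a clear error).
#' @export
readStack <- function(path, pxSize = 1, dt = 1,
                      distanceUnit = "px", timeUnit = "frame") {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("cannot read TIFF '", path, "': ", conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  comp <- attr(pages[[1L]], "compression")
  if (!is.null(comp) && !identical(comp, "none"))
    stop("compressed TIFF not supported (compression = '", comp,
         "'); please re-save uncompressed")
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L))
    stop("unsupported bit depth: ", bits, " (expected 8 or 16)")
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of multi-channel pages
    storage.mode(p) <- "double"
    attributes(p) <- list(dim = dim(p))
    p
  })
  KymoStack(frames, bitDepth = as.integer(bits), pxSize = pxSize, dt = dt,
            distanceUnit = distanceUnit, timeUnit = timeUnit)
}

#' Write a stack as an uncompressed multi-page TIFF
#'
#' Values are written at the stack's bit depth; fractional intensities are
#' rounded to the integer grid.
#'
#' @param stack a [KymoStack-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  maxv <- 2^bitDepth(stack) - 1
  pages <- lapply(frameData(stack), function(f) pmin(pmax(round(f), 0), maxv) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitDepth(stack)),
                  compression = "none")
  invisible(path)
}

#' Parse a frame-selection specification
#'
#' Frame specifications follow start:step:stop semantics, 1-based and
#' inclusive: \code{"2:2:8"} selects frames 2, 4, 6 and 8; \code{"a:c"}
#' uses step 1; the empty string selects every frame.
#'
#' @param spec character specification (\code{""}, \code{"a:c"} or
#'   \code{"a:b:c"}).
#' @param nFrames number of frames available.
#' @return strictly increasing integer vector of 1-based frame indices.
#' @examples
#' parseFrameSpec("2:2:8", 10)  # 2 4 6 8
#' parseFrameSpec("", 5)        # 1 2 3 4 5
#' @export
parseFrameSpec <- function(spec, nFrames) {
  nFrames <- as.integer(nFrames)
  if (is.null(spec) || !nzchar(trimws(spec))) return(seq_len(nFrames))
  parts <- strsplit(trimws(spec), ":", fixed = TRUE)[[1L]]
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num)) || !length(parts) %in% c(2L, 3L) ||
      any(num != round(num)))
    stop("invalid frame spec '", spec, "': expected 'start:stop' or 'start:step:stop'")
  if (length(parts) == 2L) { a <- num[1]; b <- 1; c <- num[2] }
  else { a <- num[1]; b <- num[2]; c <- num[3] }
  if (b <= 0) stop("frame spec step must be positive, got ", b)
  if (a < 1 || c > nFrames || a > c)
    stop("frame spec '", spec, "' out of range for ", nFrames, " frames")
  as.integer(seq(a, c, by = b))
}

#' Read / write a line-of-interest coordinate file
#'
#' LOI files are tab-delimited text with a header line and columns \code{X}
#' and \code{Y}: 1-based pixel coordinates of the polyline vertices
#' (x = column, y = row). The same layout is written as
#' \code{LOIselection.txt} by [writeOutputs()].
#'
#' @param path file path.
#' @param width sampling width to attach to the loaded polyline (1, 3 or 5).
#' @return [readLOI()] returns a [LineOfInterest-class]; [writeLOI()] returns
#'   the path invisibly.
#' @export
readLOI <- function(path, width = 1L) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  names(d) <- toupper(names(d))
  if (!all(c("X", "Y") %in% names(d)))
    stop("LOI file must have tab-delimited columns X and Y: ", path)
  LineOfInterest(cbind(d$X, d$Y), width = width)
}

#' @rdname readLOI
#' @param loi a [LineOfInterest-class] to write.
#' @export
writeLOI <- function(loi, path) {
  v <- loiVertices(loi)
  utils::write.table(data.frame(X = v[, 1], Y = v[, 2]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis run parameters
#'
#' Bundles every tunable of the detection/tracking pipeline. \code{lambda1}
#' is the peak search radius in pixels (maximum |column change| allowed when
#' linking successive rows), \code{lambda2} the minimum track length (tracks
#' with \code{<= lambda2} nodes are discarded), \code{omega1}/\code{omega2}
#' the time (frames) and distance (pixels) windows for branch-event
#' detection.
#'
#' @param frameSpec frame-selection string (see [parseFrameSpec()]).
#' @param loiWidth sampling width: 1, 3 or 5 pixels.
#' @param peakMethod "findpeaks", "watershed" or "canny".
#' @param lambda1 peak search radius, pixels (> 0).
#' @param lambda2 minimum track length, nodes (>= 0).
#' @param removeRedundant drop tracks sharing >= 1/3 of their nodes with a
#'   longer track.
#' @param linkBranches detect split/merge events.
#' @param omega1,omega2 branch windows: frames / pixels (>= 0).
#' @param gapTolerance extra rows a track may go unextended before it is
#'   closed (default 0: strictly successive rows).
#' @param subpixel apply 3-point parabolic sub-pixel refinement to peak
#'   positions (default FALSE; all accuracy figures in this package are
#'   quoted for integer-column detection).
#' @param saddleMin watershed basin-merge depth, grey levels.
#' @param cannySigma,cannyLow,cannyHigh 1-D Canny smoothing s.d. (columns)
#'   and hysteresis fractions of the maximum gradient magnitude.
#' @param seed integer seed recorded with the run (NA if unused).
#' @return a named list of class \code{"KymoParams"}.
#' @export
KymoParams <- function(frameSpec = "", loiWidth = 1L,
                       peakMethod = c("findpeaks", "watershed", "canny"),
                       lambda1 = 3, lambda2 = 5,
                       removeRedundant = FALSE, linkBranches = FALSE,
                       omega1 = 2, omega2 = 2, gapTolerance = 0L,
                       subpixel = FALSE, saddleMin = 1,
                       cannySigma = 1, cannyLow = 0.4, cannyHigh = 0.8,
                       seed = NA_integer_) {
  peakMethod <- match.arg(peakMethod)
  stopifnot(lambda1 > 0, lambda2 >= 0, omega1 >= 0, omega2 >= 0,
            loiWidth %in% c(1L, 3L, 5L), gapTolerance >= 0)
  structure(list(
    frameSpec = frameSpec, loiWidth = as.integer(loiWidth),
    peakMethod = peakMethod, lambda1 = lambda1, lambda2 = lambda2,
    removeRedundant = removeRedundant, linkBranches = linkBranches,
    omega1 = omega1, omega2 = omega2, gapTolerance = as.integer(gapTolerance),
    subpixel = subpixel, saddleMin = saddleMin,
    cannySigma = cannySigma, cannyLow = cannyLow, cannyHigh = cannyHigh,
    seed = seed
  ), class = "KymoParams")
}

fmt6 <- function(x) {
  # 6 significant digits, stable text for regression-friendly diffs
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 6, format = "g")))
}

writeTable <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], fmt6)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the analysis output files
#'
#' Writes the six tab-delimited result files of a run into \code{outDir}
#' (created if needed), under a per-LOI subfolder \code{"amtrak-<n>"} so
#' multiple lines of interest from one stack do not collide:
#' \itemize{
#'   \item \code{LOIselection.txt}: LOI vertex coordinates (X, Y, pixels).
#'   \item \code{USER_TrackStats.txt}: per-track duration, speed,
#'     net velocity, tortuosity, mean and s.d. of instantaneous velocity.
#'   \item \code{USER_InstStats.txt}: per-step time interval, displacement
#'     magnitude, signed displacement (leftwards negative, rightwards
#'     positive), instantaneous and signed velocity, cumulative time.
#'   \item \code{Tracklist.txt}: per-node position (pixels from the origin,
#'     i.e. the line start), frame, grey-value intensity normalized by the
#'     image bit depth (0-1), and time-frame rebased so each track starts
#'     at 0.
#'   \item \code{Branchpoints.txt}: for each detected branch, the track that
#'     splits off from or joins another track, the position (user distance
#'     units from the origin) and the time point (user time units).
#'   \item \code{All_Parameters.txt}: every user input of the run, so the
#'     analysis can be reproduced from this file plus the input TIFF and LOI.
#' }
#' Numbers are printed with 6 significant digits. An empty track set yields
#' files with headers only.
#'
#' @param tracks a [TrackSet-class].
#' @param kymo the [Kymograph-class] the tracks were made on.
#' @param loi the [LineOfInterest-class] used.
#' @param params a [KymoParams()] list.
#' @param outDir output directory.
#' @param loiIndex subfolder number (default 1 -> \code{amtrak-1}).
#' @param inputs optional named character vector of input file paths to
#'   record in \code{All_Parameters.txt}.
#' @return the subfolder path, invisibly.
#' @export
writeOutputs <- function(tracks, kymo, loi, params, outDir, loiIndex = 1L,
                         inputs = character()) {
  sub <- file.path(outDir, sprintf("amtrak-%d", as.integer(loiIndex)))
  ok <- dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(sub)) stop("cannot create output directory: ", sub)

  writeLOI(loi, file.path(sub, "LOIselection.txt"))

  ids <- trackIds(tracks)
  px <- pixelSize(kymo); dtv <- frameInterval(kymo)

  ts <- do.call(rbind, lapply(ids, function(i) {
    s <- trackSummary(trackNodes(tracks, i), px, dtv)
    data.frame(Track = i, Duration = s$duration, Speed = s$speed,
               NetVelocity = s$netVelocity, Tortuosity = s$tortuosity,
               MeanInstVelocity = s$meanInstVelocity,
               SDInstVelocity = s$sdInstVelocity)
  }))
  if (is.null(ts))
    ts <- data.frame(Track = integer(), Duration = numeric(), Speed = numeric(),
                     NetVelocity = numeric(), Tortuosity = numeric(),
                     MeanInstVelocity = numeric(), SDInstVelocity = numeric())
  writeTable(ts, file.path(sub, "USER_TrackStats.txt"))

  is_ <- do.call(rbind, lapply(ids, function(i) {
    s <- instantaneousStats(trackNodes(tracks, i), px, dtv)
    if (!nrow(s)) return(NULL)
    cbind(Track = i, s)
  }))
  if (is.null(is_))
    is_ <- cbind(Track = integer(),
                 instantaneousStats(data.frame(frame = integer(), column = numeric()), px, dtv))
  names(is_) <- c("Track", "TimeInterval", "Displacement", "SignedDisplacement",
                  "InstVelocity", "SignedVelocity", "CumulativeTime")
  writeTable(is_, file.path(sub, "USER_InstStats.txt"))

  tl <- do.call(rbind, lapply(ids, function(i) {
    tr <- intensityTrace(trackNodes(tracks, i), kymo)
    data.frame(Track = i, Position = tr$column, Frame = tr$frame,
               NormIntensity = tr$normIntensity, NormFrame = tr$normFrame)
  }))
  if (is.null(tl))
    tl <- data.frame(Track = integer(), Position = numeric(), Frame = integer(),
                     NormIntensity = numeric(), NormFrame = numeric())
  writeTable(tl, file.path(sub, "Tracklist.txt"))

  br <- branchEvents(tracks)
  bp <- data.frame(Track = br$track, ParentTrack = br$parent,
                   Distance = br$column * px, Time = br$frame * dtv,
                   Direction = br$direction)
  writeTable(bp, file.path(sub, "Branchpoints.txt"))

  pl <- params[!vapply(params, is.null, logical(1))]
  kv <- data.frame(
    Parameter = c(names(inputs), "px_size", "dt", "distance_unit", "time_unit",
                  names(pl)),
    Value = c(unname(inputs), fmt6(px), fmt6(dtv), kymo@distanceUnit,
              kymo@timeUnit,
              vapply(pl, function(v) paste(format(v), collapse = ","), character(1)))
  )
  utils::write.table(kv, file.path(sub, "All_Parameters.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sub)
}
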