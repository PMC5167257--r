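#' Convolution kernels for the bead simulator
#'
#' \code{diskKernel} is a pixelized disk of the given radius (pixels whose
#' center distance is at most the radius; 5x5 support for radius 2),
#' normalized to unit sum. \code{meanKernel} is a size x size averaging
#' kernel.
#'
#' @param radius disk radius in pixels (default 2).
#' @param size averaging kernel side (default 3).
#' @return a numeric matrix summing to 1.
#' @export
diskKernel <- function(radius = 2L) {
  off <- seq.int(-radius, radius)
  d2 <- outer(off, off, function(i, j) i * i + j * j)
  k <- (d2 <= radius^2) * 1
  k / sum(k)
}

#' @rdname diskKernel
#' @export
meanKernel <- function(size = 3L) matrix(1 / (size * size), size, size)

#' 2-D convolution with zero padding
#'
#' Direct shift-and-add convolution of an image with a small odd-sized
#' kernel; pixels beyond the image border contribute zero. For the
#' symmetric kernels used here convolution equals correlation.
#'
#' @param img numeric matrix.
#' @param kernel odd-dimensioned numeric matrix.
#' @return numeric matrix of the same shape as \code{img}.
#' @export
convolve2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L * kr, nc + 2L * kc)
  pad[(kr + 1L):(kr + nr), (kc + 1L):(kc + nc)] <- img
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w != 0)
        out <- out + w * pad[i:(i + nr - 1L), j:(j + nc - 1L)]
    }
  }
  out
}

#' Generate a synthetic fluorescent-bead time-series with ground truth
#'
#' Emulates a point-source test image: beads start as equally spaced single
#' white pixels (intensity 255) on a black background of an 8-bit frame,
#' optionally undergo a 1-D Gaussian random walk along the row axis (each
#' frame adds a Normal(0, walkSd) displacement per bead), and every frame
#' is convolved with a normalized 5x5 disk filter followed by a 3x3
#' averaging filter, then rescaled so the pre-noise peak equals 255 and
#' rounded to the integer grid. The unrounded walk position is kept as the
#' ground truth; rendering rounds it to the pixel grid, so sub-pixel
#' positional errors are measurable even with integer detection. Beads
#' walking outside the frame are clipped to the bounds and flagged in the
#' truth table.
#'
#' @param nBeads number of beads (default 3).
#' @param spacing bead spacing in pixels (default 16; must leave the 5x5
#'   kernels non-overlapping at rest, i.e. spacing > 6, else a warning).
#' @param nFrames number of frames (default 50).
#' @param imageSize c(nrow, ncol) of each frame (default 64 x 64).
#' @param walkSd random-walk step s.d. in pixels/frame (0 = static).
#' @param beadRow image row holding the beads (default: middle row).
#' @param seed integer seed for the walk (NULL: current RNG state).
#' @return a [SyntheticScene-class]; the scene's \code{truth} has one row
#'   per bead per frame with the unrounded position \code{x}.
#' @export
generateBeadStack <- function(nBeads = 3L, spacing = 16L, nFrames = 50L,
                              imageSize = c(64L, 64L), walkSd = 0,
                              beadRow = NULL, seed = NULL) {
  stopifnot(nBeads >= 1L, nFrames >= 1L, walkSd >= 0)
  if (spacing <= 6) warning("spacing <= 6 px: 5x5 bead kernels overlap at rest")
  if (!is.null(seed)) set.seed(seed)
  nr <- imageSize[1L]; nc <- imageSize[2L]
  if (is.null(beadRow)) beadRow <- (nr + 1L) %/% 2L
  # equally spaced initial positions, centered in the row
  span <- (nBeads - 1L) * spacing
  if (span > nc - 6L) stop("beads do not fit in the image at this spacing")
  x0 <- (nc - span) / 2 + spacing * (seq_len(nBeads) - 1L)
  x0 <- round(x0)  # start on the pixel grid ("single white pixels")
  pos <- matrix(0, nFrames, nBeads)
  pos[1L, ] <- x0
  if (nFrames > 1L) for (t in 2:nFrames)
    pos[t, ] <- pos[t - 1L, ] + stats::rnorm(nBeads, 0, walkSd)
  clipped <- pos < 3 | pos > nc - 2
  pos <- pmin(pmax(pos, 3), nc - 2)
  disk <- diskKernel(2L)
  avg <- meanKernel(3L)
  raw <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    f <- matrix(0, nr, nc)
    f[beadRow, round(pos[t, ])] <- 255
    raw[[t]] <- convolve2d(convolve2d(f, disk), avg)
  }
  peak <- max(vapply(raw, max, numeric(1)))
  frames <- lapply(raw, function(f) round(f * (255 / peak)))
  truth <- data.frame(
    frame = rep(seq_len(nFrames), each = nBeads),
    bead = rep(seq_len(nBeads), nFrames),
    x = as.vector(t(pos)),
    clipped = as.vector(t(clipped))
  )
  params <- list(nBeads = nBeads, spacing = spacing, nFrames = nFrames,
                 imageSize = imageSize, beadRow = beadRow, walkSd = walkSd,
                 noiseSd = 0, seed = if (is.null(seed)) NA_integer_ else seed)
  new("SyntheticScene",
      stack = KymoStack(frames, bitDepth = 8L),
      truth = truth, params = params)
}

#' Add zero-mean Gaussian intensity noise to a stack
#'
#' Independent Normal(0, noiseSd) values are added per pixel per frame,
#' then clipped to the bit-depth range and rounded to the integer grid
#' (the behavior of ImageJ's "Specified Noise").
#'
#' @param x a [KymoStack-class] or [SyntheticScene-class].
#' @param noiseSd noise standard deviation in grey levels (>= 0).
#' @param seed integer seed (NULL: current RNG state).
#' @return the same class as \code{x}, with noisy frames (a scene records
#'   \code{noiseSd} in its params).
#' @export
addGaussianNoise <- function(x, noiseSd, seed = NULL) {
  stopifnot(noiseSd >= 0)
  stack <- if (is(x, "SyntheticScene")) sceneStack(x) else x
  if (noiseSd == 0) {
    noisy <- stack
  } else {
    if (!is.null(seed)) set.seed(seed)
    maxv <- 2^bitDepth(stack) - 1
    frames <- lapply(frameData(stack), function(f) {
      g <- f + stats::rnorm(length(f), 0, noiseSd)
      matrix(pmin(pmax(round(g), 0), maxv), nrow(f), ncol(f))
    })
    noisy <- initialize(stack, frames = frames)
  }
  if (is(x, "SyntheticScene")) {
    p <- x@params; p$noiseSd <- noiseSd
    initialize(x, stack = noisy, params = p)
  } else noisy
}

#' The natural line of interest of a bead scene
#'
#' A horizontal line through the bead row, spanning the full frame width,
#' with the given sampling width.
#'
#' @param scene a [SyntheticScene-class].
#' @param width LOI width (default 1).
#' @return a [LineOfInterest-class].
#' @export
sceneLOI <- function(scene, width = 1L) {
  nc <- ncol(frameData(sceneStack(scene))[[1L]])
  r <- scene@params$beadRow
  LineOfInterest(rbind(c(1, r), c(nc, r)), width = width)
}

#' Positional accuracy of tracking against ground truth
#'
#' Per frame, every detected track node is matched to the nearest true bead
#' position in that frame (nearest neighbor, capped at \code{cap} pixels;
#' unmatched nodes are excluded and counted). The positional error is
#' dx = |x_true - x_detected|, collected over all matched nodes. Reported
#' are the arithmetic mean of dx and the mean from an exponential-decay fit
#' to the normalized frequency distribution of dx (fit mean m = 1/b for
#' y = A e^(-b x)); the fit mean is the more representative central
#' tendency because the arithmetic mean underestimates the error at high
#' noise. When every error is (numerically) zero both means are 0 and the
#' fit is flagged degenerate.
#'
#' @param tracks a [TrackSet-class] from the pipeline.
#' @param truth ground-truth data.frame (\code{frame}, \code{bead},
#'   \code{x}) from a [SyntheticScene-class].
#' @param kymo the [Kymograph-class] the tracks were made on (maps node
#'   columns to image x coordinates via the line's sample centers).
#' @param cap matching radius in pixels (default 3, the usual search
#'   radius).
#' @return list of class \code{"AccuracyResult"}: \code{deltaX} (matched
#'   errors), \code{arithMean}, \code{fitMean}, \code{fitRsq},
#'   \code{nMatched}, \code{nUnmatched}, \code{fit} (the KymoFit),
#'   \code{flag} (character, "" when clean).
#' @export
evaluateAccuracy <- function(tracks, truth, kymo, cap = 3) {
  nodes <- trackNodes(tracks)
  empty <- structure(list(deltaX = numeric(), arithMean = NA_real_,
                          fitMean = NA_real_, fitRsq = NA_real_,
                          nMatched = 0L, nUnmatched = 0L, fit = NULL,
                          flag = "no tracks"), class = "AccuracyResult")
  if (!nrow(nodes)) return(empty)
  sc <- sampleCoords(kymo)
  # image x coordinate of a (possibly fractional) kymograph column
  colToX <- function(col) {
    j <- pmin(pmax(col, 1), nrow(sc))
    jf <- floor(j)
    frac <- j - jf
    x0 <- sc[jf, 1L]
    x1 <- sc[pmin(jf + 1L, nrow(sc)), 1L]
    x0 + frac * (x1 - x0)
  }
  xD <- colToX(nodes$column)
  dx <- numeric(0)
  unmatched <- 0L
  for (f in unique(nodes$frame)) {
    xs <- truth$x[truth$frame == f]
    if (!length(xs)) { unmatched <- unmatched + sum(nodes$frame == f); next }
    for (x in xD[nodes$frame == f]) {
      d <- min(abs(xs - x))
      if (d <= cap) dx <- c(dx, d) else unmatched <- unmatched + 1L
    }
  }
  if (!length(dx)) { empty$flag <- "no matched nodes"; return(empty) }
  am <- mean(dx)
  if (all(dx < 1e-9)) {
    return(structure(list(deltaX = dx, arithMean = 0, fitMean = 0,
                          fitRsq = NA_real_, nMatched = length(dx),
                          nUnmatched = unmatched, fit = NULL,
                          flag = "all errors zero (degenerate fit)"),
                     class = "AccuracyResult"))
  }
  fit <- fitExponentialDecay(dx, positiveOnly = FALSE)
  structure(list(deltaX = dx, arithMean = am,
                 fitMean = if (fit$converged) fit$m else NA_real_,
                 fitRsq = fit$rsq, nMatched = length(dx),
                 nUnmatched = unmatched, fit = fit,
                 flag = if (fit$converged) "" else fit$message),
            class = "AccuracyResult")
}

#' @export
print.AccuracyResult <- function(x, ...) {
  cat(sprintf("AccuracyResult: %d matched node(s), %d unmatched\n",
              x$nMatched, x$nUnmatched))
  cat(sprintf("  arithmetic mean dx = %.4g px; exponential-fit mean = %.4g px (R^2 = %.3f)\n",
              x$arithMean, x$fitMean, if (is.na(x$fitRsq)) NA else x$fitRsq))
  if (nzchar(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Run the tracking pipeline on a synthetic scene
#'
#' Convenience wrapper: builds the kymograph along the scene's bead row,
#' segments, detects, links, prunes and (optionally) evaluates accuracy.
#'
#' @param scene a [SyntheticScene-class] (noise already added if wanted).
#' @param params a [KymoParams()] list (defaults: findpeaks, lambda1 = 3,
#'   lambda2 = 5).
#' @return list with \code{kymo}, \code{tracks}, \code{accuracy}.
#' @export
analyzeScene <- function(scene, params = KymoParams()) {
  loi <- sceneLOI(scene, width = params$loiWidth)
  stack <- sceneStack(scene)
  frames <- parseFrameSpec(params$frameSpec, nFrames(stack))
  kymo <- buildKymograph(stack, loi, frames)
  tracks <- trackKymograph(kymo, params)
  acc <- evaluateAccuracy(tracks, groundTruth(scene), kymo, cap = params$lambda1)
  list(kymo = kymo, tracks = tracks, accuracy = acc)
}

#' Sweep noise or walk amplitude and measure positional accuracy
#'
#' For each sweep value, generates \code{nReps} scenes (sub-seeded
#' deterministically from \code{seed}), runs the full pipeline, pools the
#' positional errors over the repetitions and reports both the arithmetic
#' and the exponential-fit mean.
#'
#' @param sweep "noise" (vary the noise s.d. at fixed walk s.d.) or "walk"
#'   (vary the walk s.d. at fixed noise s.d.).
#' @param values non-negative sweep values (grey levels or px/frame).
#' @param nReps repetitions per value (default 3).
#' @param noiseSd,walkSd the fixed parameter of the non-swept axis.
#' @param params pipeline parameters ([KymoParams()]).
#' @param seed base integer seed; rep r of value v uses
#'   \code{seed + 101 * index} style sub-seeds, kept below 2^31.
#' @param ... passed to [generateBeadStack()] (nBeads, spacing, nFrames,
#'   imageSize).
#' @return data.frame, one row per sweep value: \code{value},
#'   \code{arithMean}, \code{fitMean}, \code{fitRsq}, \code{nMatched},
#'   \code{nUnmatched}, \code{flag}.
#' @export
accuracySweep <- function(sweep = c("noise", "walk"), values, nReps = 3L,
                          noiseSd = 0, walkSd = 0, params = KymoParams(),
                          seed = 1L, ...) {
  sweep <- match.arg(sweep)
  stopifnot(all(values >= 0))
  rows <- vector("list", length(values))
  for (vi in seq_along(values)) {
    dxAll <- numeric(0)
    nm <- 0L; nu <- 0L
    for (r in seq_len(nReps)) {
      sub <- (seed + 7919L * (vi - 1L) + 101L * r) %% 2147483647L
      ws <- if (sweep == "walk") values[vi] else walkSd
      ns <- if (sweep == "noise") values[vi] else noiseSd
      scene <- generateBeadStack(walkSd = ws, seed = sub, ...)
      scene <- addGaussianNoise(scene, ns, seed = sub + 1L)
      res <- analyzeScene(scene, params)
      dxAll <- c(dxAll, res$accuracy$deltaX)
      nm <- nm + res$accuracy$nMatched
      nu <- nu + res$accuracy$nUnmatched
    }
    if (!length(dxAll)) {
      rows[[vi]] <- data.frame(value = values[vi], arithMean = NA_real_,
                               fitMean = NA_real_, fitRsq = NA_real_,
                               nMatched = 0L, nUnmatched = nu,
                               flag = "no matches")
      next
    }
    am <- mean(dxAll)
    if (all(dxAll < 1e-9)) {
      rows[[vi]] <- data.frame(value = values[vi], arithMean = 0, fitMean = 0,
                               fitRsq = NA_real_, nMatched = nm,
                               nUnmatched = nu, flag = "all errors zero")
      next
    }
    fit <- fitExponentialDecay(dxAll, positiveOnly = FALSE)
    rows[[vi]] <- data.frame(
      value = values[vi], arithMean = am,
      fitMean = if (fit$converged) fit$m else NA_real_,
      fitRsq = fit$rsq, nMatched = nm, nUnmatched = nu,
      flag = if (fit$converged) "" else fit$message)
  }
  do.call(rbind, rows)
}
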