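#' Otsu threshold of a 1-D intensity profile
#'
#' Exhaustive search over all candidate thresholds (the distinct profile
#' values except the largest): the threshold maximizing the between-class
#' variance w0*w1*(mu0 - mu1)^2 of the two classes {v <= t} and {v > t}.
#' Ties are broken towards the lowest threshold. A profile with zero
#' variance has no threshold (returns NA).
#'
#' @param v numeric vector of intensities.
#' @return the threshold, or NA for a degenerate (constant) profile.
#' @export
otsuThreshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  # split after the last occurrence of each candidate value
  k <- findInterval(u[-length(u)], vs)
  w0 <- k / n
  w1 <- 1 - w0
  mu0 <- cs[k] / k
  mu1 <- (cs[n] - cs[k]) / (n - k)
  sb <- w0 * w1 * (mu0 - mu1)^2
  u[which.max(sb)]  # which.max takes the first (lowest) maximizer
}

#' Row-wise Otsu segmentation of a kymograph
#'
#' Each row is thresholded independently with [otsuThreshold()]; pixels
#' strictly above the row's threshold are foreground. Rows with zero
#' intensity variance yield an all-background row.
#'
#' @param kymo a [Kymograph-class].
#' @return logical T x L matrix (TRUE = foreground).
#' @export
segmentRows <- function(kymo) {
  vals <- kymoValues(kymo)
  mask <- matrix(FALSE, nrow(vals), ncol(vals))
  for (t in seq_len(nrow(vals))) {
    th <- otsuThreshold(vals[t, ])
    if (!is.na(th)) mask[t, ] <- vals[t, ] > th
  }
  mask
}

# Local maxima of a 1-D profile with plateau handling: runs of equal value
# strictly greater than both neighboring values are maxima; a plateau
# reports its center column (floor of the midpoint). Values outside the
# profile (and masked-out samples) are treated as -Inf, so a run touching
# the profile end counts when it exceeds its single interior neighbor.
localMaxima <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  isPeak <- is.finite(r$values) & r$values > left & r$values > right
  as.integer(floor((starts[isPeak] + ends[isPeak]) / 2))
}

# 1-D watershed on a masked profile: one peak per catchment basin of the
# inverted profile, restricted to foreground. Basins separated by a saddle
# shallower than saddleMin grey levels are merged (the lower peak is
# suppressed; ties keep the earlier column).
watershedPeaks1d <- function(v, fg, saddleMin = 1) {
  peaks <- integer()
  runs <- rle(fg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (ri in which(runs$values)) {
    a <- starts[ri]; b <- ends[ri]
    seg <- v[a:b]
    p <- localMaxima(seg)
    if (!length(p)) next
    # merge basins across shallow saddles
    repeat {
      if (length(p) < 2L) break
      h <- seg[p]
      depth <- numeric(length(p) - 1L)
      for (i in seq_len(length(p) - 1L)) {
        saddle <- min(seg[p[i]:p[i + 1L]])
        depth[i] <- min(h[i], h[i + 1L]) - saddle
      }
      i <- which.min(depth)
      if (depth[i] >= saddleMin) break
      drop <- if (h[i] < h[i + 1L]) i else if (h[i] > h[i + 1L]) i + 1L else i + 1L
      p <- p[-drop]
    }
    peaks <- c(peaks, p + a - 1L)
  }
  peaks
}

# 3-point parabolic sub-pixel refinement around an integer peak column.
parabolicRefine <- function(v, j) {
  if (j <= 1L || j >= length(v)) return(j)
  y0 <- v[j - 1L]; y1 <- v[j]; y2 <- v[j + 1L]
  den <- y0 - 2 * y1 + y2
  if (den >= 0) return(j)
  j + 0.5 * (y0 - y2) / den
}

#' Detect per-row intensity peaks in a kymograph
#'
#' For every row independently, returns the positions of object centers in
#' the foreground of the row mask:
#' \itemize{
#'   \item \code{"findpeaks"}: local maxima of the masked intensity profile
#'     (samples strictly greater than both neighbors; a flat-topped maximum
#'     reports its center column).
#'   \item \code{"watershed"}: one peak per catchment basin of the inverted
#'     masked profile, at the basin's intensity maximum; basins separated by
#'     a saddle shallower than \code{saddleMin} grey levels are merged to
#'     suppress noise-splitting.
#' }
#' Peaks outside foreground are discarded. Both methods are ideal for
#' spherical objects; use [detectEdges()] when edges are the more reliable
#' descriptor (e.g. filament tips).
#'
#' @param kymo a [Kymograph-class].
#' @param mask logical foreground mask from [segmentRows()].
#' @param method "findpeaks" or "watershed".
#' @param saddleMin watershed basin-merge depth in grey levels (default 1).
#' @param subpixel apply 3-point parabolic refinement to peak columns
#'   (default FALSE: integer columns).
#' @return data.frame (one row per peak): \code{row}, \code{column},
#'   \code{intensity} (raw grey value), \code{kind} = "center"; within each
#'   row, columns strictly increasing.
#' @export
detectPeaks <- function(kymo, mask, method = c("findpeaks", "watershed"),
                        saddleMin = 1, subpixel = FALSE) {
  method <- match.arg(method)
  vals <- kymoValues(kymo)
  out <- vector("list", nrow(vals))
  for (t in seq_len(nrow(vals))) {
    v <- vals[t, ]
    fg <- mask[t, ]
    if (!any(fg)) next
    if (method == "findpeaks") {
      vm <- ifelse(fg, v, -Inf)
      p <- localMaxima(vm)
    } else {
      p <- watershedPeaks1d(v, fg, saddleMin = saddleMin)
    }
    p <- p[fg[p]]
    if (!length(p)) next
    col <- if (subpixel) vapply(p, function(j) parabolicRefine(v, j), numeric(1)) else as.numeric(p)
    out[[t]] <- data.frame(row = t, column = col, intensity = v[p],
                           kind = "center", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(row = integer(), column = numeric(),
                      intensity = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# 1-D Canny edge positions on a profile: Gaussian smoothing (s.d. sigma
# columns), central-difference gradient, non-maximum suppression of the
# gradient magnitude, hysteresis: contiguous above-low segments are kept if
# they contain an above-high sample. Returns columns and gradient signs.
cannyEdges1d <- function(v, sigma = 1, low = 0.4, high = 0.8) {
  n <- length(v)
  if (n < 3L) return(list(pos = integer(), sign = integer()))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- c(rep(v[1L], r), v, rep(v[n], r))
  sm <- stats::filter(pad, k, sides = 2)[(r + 1L):(r + n)]
  g <- c(sm[2L] - sm[1L], (sm[3:n] - sm[1:(n - 2L)]) / 2, sm[n] - sm[n - 1L])
  mag <- abs(g)
  mx <- max(mag)
  if (mx == 0) return(list(pos = integer(), sign = integer()))
  nms <- localMaxima(mag)
  if (!length(nms)) return(list(pos = integer(), sign = integer()))
  strong <- mag >= high * mx
  weak <- mag >= low * mx
  segs <- rle(weak)
  sends <- cumsum(segs$lengths)
  sstarts <- sends - segs$lengths + 1L
  keepSeg <- segs$values & vapply(seq_along(segs$values), function(i)
    segs$values[i] && any(strong[sstarts[i]:sends[i]]), logical(1))
  keep <- logical(n)
  for (i in which(keepSeg)) keep[sstarts[i]:sends[i]] <- TRUE
  pos <- nms[keep[nms]]
  list(pos = pos, sign = sign(g[pos]))
}

#' Detect per-row object edges in a kymograph
#'
#' For every row, the left and right boundary positions of each foreground
#' object, taken from 1-D Canny edge responses on the row profile: the
#' rising edge nearest the object's left boundary becomes an "edge-left"
#' peak and the falling edge nearest its right boundary an "edge-right"
#' peak (falling back to the mask boundary itself when no Canny response
#' lies within the object's neighborhood). The two edge families are
#' trackable independently, e.g. the two tips of a gliding filament.
#'
#' @inheritParams detectPeaks
#' @param sigma Gaussian smoothing s.d. in columns (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.4 / 0.8).
#' @return data.frame as in [detectPeaks()] with kinds "edge-left" and
#'   "edge-right"; rows with no foreground yield no edges.
#' @export
detectEdges <- function(kymo, mask, sigma = 1, low = 0.4, high = 0.8) {
  vals <- kymoValues(kymo)
  out <- list()
  for (t in seq_len(nrow(vals))) {
    fg <- mask[t, ]
    if (!any(fg)) next
    v <- vals[t, ]
    ce <- cannyEdges1d(v, sigma = sigma, low = low, high = high)
    runs <- rle(fg)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      a <- starts[ri]; b <- ends[ri]
      halo <- max(3L, ceiling(3 * sigma))
      rising <- ce$pos[ce$sign > 0 & ce$pos >= a - halo & ce$pos <= b]
      falling <- ce$pos[ce$sign < 0 & ce$pos >= a & ce$pos <= b + halo]
      el <- if (length(rising)) rising[which.min(abs(rising - a))] else a
      er <- if (length(falling)) falling[which.min(abs(falling - b))] else b
      out[[length(out) + 1L]] <- data.frame(
        row = t, column = as.numeric(c(el, er)),
        intensity = v[c(el, er)],
        kind = c("edge-left", "edge-right"), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(row = integer(), column = numeric(),
                      intensity = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$row, res$column), , drop = FALSE]
  rownames(res) <- NULL
  res
}
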