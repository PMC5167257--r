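# Independent brute-force oracles used to freeze expected values.
# Deliberately written with loops / enumeration, sharing no code with the
# package implementations they check.

# Otsu: try every candidate threshold, compute between-class variance from
# first principles (class weights and means by explicit subsetting).
oracleOtsu <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(NA_real_)
  best <- -Inf; bt <- NA_real_
  for (t in u[-length(u)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    sb <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; bt <- t }
  }
  bt
}

# Local maxima: explicit scan for samples strictly greater than both
# neighbors (no plateau logic; use on profiles with distinct values).
oracleLocalMax <- function(v) {
  out <- integer()
  for (i in seq_along(v)) {
    l <- if (i > 1) v[i - 1] else -Inf
    r <- if (i < length(v)) v[i + 1] else -Inf
    if (is.finite(v[i]) && v[i] > l && v[i] > r) out <- c(out, i)
  }
  out
}

# Grid line rasterization by stepping the major axis and rounding the
# minor coordinate (matches 8-connected Bresenham for half-integer-free
# slopes; use on segments where rounding is unambiguous).
oracleLineRaster <- function(x0, y0, x1, y1) {
  if (abs(x1 - x0) >= abs(y1 - y0)) {
    xs <- seq(x0, x1, by = sign(x1 - x0))
    cbind(x = xs, y = round(y0 + (xs - x0) * (y1 - y0) / (x1 - x0)))
  } else {
    ys <- seq(y0, y1, by = sign(y1 - y0))
    cbind(x = round(x0 + (ys - y0) * (x1 - x0) / (y1 - y0)), y = ys)
  }
}

# Exhaustive minimal-sum bipartite matching between two rows of peak
# columns under a search radius: enumerate all injective assignments of
# next-row peaks to current-row peaks (<= 3 per row) and minimize the
# total |dcolumn|, leaving peaks unmatched where no pairing <= lambda1
# exists.
oracleRowMatch <- function(cols0, cols1, lambda1) {
  n0 <- length(cols0); n1 <- length(cols1)
  idx1 <- c(seq_len(n1), rep(NA_integer_, max(0, n0 - n1)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- NULL; bestCost <- Inf; bestN <- -1
  for (p in unique(perms(idx1))) {
    assign <- p[seq_len(n0)]
    cost <- 0; nlink <- 0; ok <- TRUE
    for (i in seq_len(n0)) {
      j <- assign[i]
      if (!is.na(j)) {
        d <- abs(cols0[i] - cols1[j])
        if (d > lambda1) { ok <- FALSE; break }
        cost <- cost + d; nlink <- nlink + 1
      }
    }
    if (!ok) next
    if (nlink > bestN || (nlink == bestN && cost < bestCost - 1e-12)) {
      best <- assign; bestCost <- cost; bestN <- nlink
    }
  }
  best
}

# A small TrackSet from a list of node data.frames (frame, column), for
# constructing pruning/branching cases directly.
makeTracks <- function(nodeList, kind = "center") {
  nodes <- do.call(rbind, lapply(seq_along(nodeList), function(i) {
    d <- nodeList[[i]]
    data.frame(track = i, row = d$frame, frame = d$frame, column = d$column,
               intensity = if (is.null(d$intensity)) 100 else d$intensity,
               kind = kind, stringsAsFactors = FALSE)
  }))
  new("TrackSet", nodes = nodes)
}

# Default pipeline parameters used throughout the accuracy tests.
accuracyParams <- function() KymoParams(peakMethod = "findpeaks", lambda1 = 3, lambda2 = 5)
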