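#' Resolve equidistant link candidates by the largest-angle rule
#'
#' When two or more candidate peaks in the next processed row lie at the
#' same |column| distance from a track's last node, the candidate making the
#' largest angle (0 to pi) with the existing track is chosen: the angle at
#' the last node between the vector pointing back to the previous node and
#' the vector pointing to the candidate, measured in (row, column) space.
#' An angle of pi is a straight continuation, so the straightest
#' continuation wins. Remaining ties (exactly symmetric candidates) take
#' the lowest column; a track with a single node has no back-vector and
#' also takes the lowest column (with a warning).
#'
#' @param lastNode numeric c(row, column) of the track's last node.
#' @param prevNode numeric c(row, column) of the node before it, or NULL
#'   for a 1-node track.
#' @param candidates numeric matrix with columns \code{row}, \code{column}
#'   (>= 1 rows).
#' @return the index (row of \code{candidates}) of the chosen peak.
#' @export
resolveEquidistant <- function(lastNode, prevNode, candidates) {
  if (nrow(candidates) == 1L) return(1L)
  ord <- order(candidates[, "column"])
  if (is.null(prevNode)) {
    warning("equidistant candidates at a track's first extension; taking the lowest column")
    return(ord[1L])
  }
  u <- c(prevNode[1L] - lastNode[1L], prevNode[2L] - lastNode[2L])
  ang <- apply(candidates, 1L, function(cand) {
    v <- c(cand["row"] - lastNode[1L], cand["column"] - lastNode[2L])
    cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    acos(pmin(pmax(cosang, -1), 1))
  })
  # largest angle wins; ties by lowest column
  best <- max(ang)
  tied <- which(ang >= best - 1e-12)
  tied[which.min(candidates[tied, "column"])]
}

#' Link per-row peaks into tracks by distance minimization
#'
#' Greedy row-by-row extension over the processed kymograph rows: active
#' tracks (longest first, ties by track id) each claim the unclaimed peak in
#' the next row minimizing |column change|, provided that distance is at
#' most \code{lambda1} (the peak search radius). Equidistant candidates are
#' resolved by [resolveEquidistant()]. Each peak joins at most one track;
#' peaks never claimed start new tracks. A track not extended for more than
#' \code{gapTolerance} rows is closed (default 0: strictly successive rows).
#' Peak kinds (center / edge-left / edge-right) are linked independently,
#' so the two edges of a filament give two separate tracks.
#'
#' @param peaks data.frame from [detectPeaks()] or [detectEdges()].
#' @param lambda1 peak search radius in pixels (> 0).
#' @param gapTolerance extra unextended rows before a track is closed.
#' @param nRows total number of kymograph rows (default: max row in peaks).
#' @return a [TrackSet-class] (branch slot empty; see
#'   [detectBranchEvents()]).
#' @export
linkPeaks <- function(peaks, lambda1, gapTolerance = 0L, nRows = NULL) {
  stopifnot(lambda1 > 0)
  emptyNodes <- data.frame(track = integer(), row = integer(), frame = integer(),
                           column = numeric(), intensity = numeric(),
                           kind = character(), stringsAsFactors = FALSE)
  if (!nrow(peaks)) return(new("TrackSet", nodes = emptyNodes,
                               params = list(lambda1 = lambda1,
                                             gapTolerance = gapTolerance)))
  if (is.null(nRows)) nRows <- max(peaks$row)
  kinds <- unique(peaks$kind)
  allNodes <- list()
  nextId <- 1L
  for (kd in kinds) {
    pk <- peaks[peaks$kind == kd, , drop = FALSE]
    byRow <- split(pk, pk$row)
    # active track state: list(id, nodes (list of c(row, column, intensity)), gap)
    active <- list()
    closed <- list()
    for (t in seq_len(nRows)) {
      rowPeaks <- byRow[[as.character(t)]]
      claimed <- if (is.null(rowPeaks)) logical(0) else logical(nrow(rowPeaks))
      if (length(active)) {
        lens <- vapply(active, function(a) length(a$nodes), integer(1))
        ids <- vapply(active, function(a) a$id, integer(1))
        ordTr <- order(-lens, ids)
        extended <- logical(length(active))
        for (ai in ordTr) {
          a <- active[[ai]]
          if (!is.null(rowPeaks) && any(!claimed)) {
            avail <- which(!claimed)
            lastN <- a$nodes[[length(a$nodes)]]
            d <- abs(rowPeaks$column[avail] - lastN[2L])
            dmin <- min(d)
            if (dmin <= lambda1) {
              cand <- avail[d <= dmin + 1e-9]
              if (length(cand) > 1L) {
                prevN <- if (length(a$nodes) >= 2L) a$nodes[[length(a$nodes) - 1L]] else NULL
                cm <- cbind(row = rowPeaks$row[cand], column = rowPeaks$column[cand])
                pick <- resolveEquidistant(lastN[1:2], if (is.null(prevN)) NULL else prevN[1:2], cm)
                chosen <- cand[pick]
              } else chosen <- cand
              a$nodes[[length(a$nodes) + 1L]] <-
                c(t, rowPeaks$column[chosen], rowPeaks$intensity[chosen])
              a$gap <- 0L
              claimed[chosen] <- TRUE
              extended[ai] <- TRUE
              active[[ai]] <- a
            }
          }
        }
        # age and close unextended tracks
        keep <- logical(length(active))
        for (ai in seq_along(active)) {
          if (!extended[ai]) {
            active[[ai]]$gap <- active[[ai]]$gap + 1L
            if (active[[ai]]$gap > gapTolerance) {
              closed[[length(closed) + 1L]] <- active[[ai]]
            } else keep[ai] <- TRUE
          } else keep[ai] <- TRUE
        }
        active <- active[keep]
      }
      # unclaimed peaks start new tracks
      if (!is.null(rowPeaks)) {
        for (pi in which(!claimed)) {
          active[[length(active) + 1L]] <- list(
            id = nextId,
            nodes = list(c(t, rowPeaks$column[pi], rowPeaks$intensity[pi])),
            gap = 0L)
          nextId <- nextId + 1L
        }
      }
    }
    closed <- c(closed, active)
    for (a in closed) {
      m <- do.call(rbind, a$nodes)
      allNodes[[length(allNodes) + 1L]] <- data.frame(
        track = a$id, row = as.integer(m[, 1L]), frame = as.integer(m[, 1L]),
        column = m[, 2L], intensity = m[, 3L], kind = kd,
        stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, allNodes)
  if (is.null(nodes)) nodes <- emptyNodes
  nodes <- nodes[order(nodes$track, nodes$row), , drop = FALSE]
  rownames(nodes) <- NULL
  new("TrackSet", nodes = nodes,
      params = list(lambda1 = lambda1, gapTolerance = gapTolerance))
}

# Map kymograph row indices of track nodes to original frame numbers.
assignFrames <- function(tracks, kymo) {
  nodes <- tracks@nodes
  if (nrow(nodes)) nodes$frame <- frameIndices(kymo)[nodes$row]
  initialize(tracks, nodes = nodes)
}

#' Remove short tracks
#'
#' Tracks whose number of linked peaks is at most \code{lambda2} are
#' eliminated (kept iff node count > lambda2), avoiding artifacts from very
#' short tracks.
#'
#' @param tracks a [TrackSet-class].
#' @param lambda2 minimum track length in nodes (>= 0).
#' @return the filtered [TrackSet-class].
#' @export
filterShortTracks <- function(tracks, lambda2) {
  stopifnot(lambda2 >= 0)
  nodes <- tracks@nodes
  n <- table(nodes$track)
  keep <- names(n)[n > lambda2]
  nodes <- nodes[nodes$track %in% as.integer(keep), , drop = FALSE]
  rownames(nodes) <- NULL
  p <- tracks@params; p$lambda2 <- lambda2
  initialize(tracks, nodes = nodes, params = p)
}

#' Remove redundant tracks
#'
#' A track i with n_i nodes is redundant if the number n_c of its (frame,
#' column) coordinates shared exactly with any other retained track
#' satisfies n_c >= n_i / 3. Tracks are examined in increasing length
#' order, so the longer of an overlapping pair survives (longer tracks
#' carry more statistics).
#'
#' @param tracks a [TrackSet-class].
#' @return the pruned [TrackSet-class].
#' @export
removeRedundant <- function(tracks) {
  nodes <- tracks@nodes
  if (!nrow(nodes)) return(tracks)
  key <- paste(nodes$frame, nodes$column, nodes$kind, sep = "/")
  ids <- unique(nodes$track)
  lens <- vapply(ids, function(i) sum(nodes$track == i), integer(1))
  retained <- ids
  for (i in ids[order(lens, ids)]) {
    mine <- key[nodes$track == i]
    others <- key[nodes$track %in% setdiff(retained, i)]
    nc <- sum(mine %in% others)
    if (nc >= length(mine) / 3) retained <- setdiff(retained, i)
  }
  nodes <- nodes[nodes$track %in% retained, , drop = FALSE]
  rownames(nodes) <- NULL
  initialize(tracks, nodes = nodes)
}

#' Detect split/merge branch events between tracks
#'
#' For every track end-point (and, symmetrically, every start-point), the
#' nodes of other tracks lying within \code{omega1} frames and
#' \code{omega2} columns are collected; if any exist, the node minimizing
#' the Euclidean distance sqrt(dframe^2 + dcolumn^2) to the end-point
#' defines a branch event linking the child track to the parent track.
#' An end-point joining another track is a merge; a start-point leaving one
#' is a split. Each end-point yields at most one event.
#'
#' @param tracks a [TrackSet-class].
#' @param omega1 time window in frames (>= 0).
#' @param omega2 distance window in pixels (>= 0).
#' @param detectMerges,detectSplits which end of each track to evaluate
#'   (both TRUE by default).
#' @return the [TrackSet-class] with its \code{branches} slot filled:
#'   columns \code{track} (child), \code{parent}, \code{column} and
#'   \code{frame} (the matched parent node), \code{direction}
#'   ("merge"/"split").
#' @export
detectBranchEvents <- function(tracks, omega1, omega2,
                               detectMerges = TRUE, detectSplits = TRUE) {
  stopifnot(omega1 >= 0, omega2 >= 0)
  nodes <- tracks@nodes
  ev <- list()
  for (i in unique(nodes$track)) {
    tn <- nodes[nodes$track == i, , drop = FALSE]
    others <- nodes[nodes$track != i & nodes$kind == tn$kind[1L], , drop = FALSE]
    if (!nrow(others)) next
    ends <- list()
    if (detectMerges) ends$merge <- tn[nrow(tn), ]
    if (detectSplits) ends$split <- tn[1L, ]
    for (dir in names(ends)) {
      e <- ends[[dir]]
      df <- abs(others$frame - e$frame)
      dx <- abs(others$column - e$column)
      inWin <- df <= omega1 & dx <= omega2
      if (!any(inWin)) next
      dist <- sqrt(df[inWin]^2 + dx[inWin]^2)
      cand <- others[inWin, , drop = FALSE]
      # argmin; ties by lowest parent id then earliest frame
      best <- order(dist, cand$track, cand$frame)[1L]
      ev[[length(ev) + 1L]] <- data.frame(
        track = i, parent = cand$track[best], column = cand$column[best],
        frame = cand$frame[best], direction = dir, stringsAsFactors = FALSE)
    }
  }
  br <- do.call(rbind, ev)
  if (is.null(br))
    br <- data.frame(track = integer(), parent = integer(), column = numeric(),
                     frame = integer(), direction = character(),
                     stringsAsFactors = FALSE)
  p <- tracks@params; p$omega1 <- omega1; p$omega2 <- omega2
  initialize(tracks, branches = br, params = p)
}
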