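peaksFromColumns <- function(colsByRow) {
  do.call(rbind, lapply(seq_along(colsByRow), function(r) {
    cols <- colsByRow[[r]]
    if (!length(cols)) return(NULL)
    data.frame(row = r, column = cols, intensity = 100, kind = "center",
               stringsAsFactors = FALSE)
  }))
}

test_that("a stationary peak links into a single track; jumps beyond lambda1 do not link", {
  p <- peaksFromColumns(rep(list(10), 5))
  ts <- linkPeaks(p, lambda1 = 2)
  expect_equal(nTracks(ts), 1L)
  expect_equal(nrow(trackNodes(ts, 1)), 5L)

  # peak marching +3 columns/row with lambda1 = 2: five 1-node tracks
  p2 <- peaksFromColumns(as.list(seq(10, 22, by = 3)))
  ts2 <- linkPeaks(p2, lambda1 = 2)
  expect_equal(nTracks(ts2), 5L)
  expect_true(all(table(trackNodes(ts2)$track) == 1))
  # ...all removed by the length filter
  expect_equal(nTracks(filterShortTracks(ts2, 1)), 0L)
})

test_that("greedy linking matches exhaustive minimal-sum matching on separated tracks", {
  # two parallel peaks 10 columns apart drifting +-1/row
  set.seed(31)
  for (rep in 1:10) {
    drift <- sample(c(-1, 1), 8, TRUE)
    c1 <- cumsum(c(20, drift[-1]))
    c2 <- c1 + 10
    p <- peaksFromColumns(Map(c, c1, c2))
    ts <- linkPeaks(p, lambda1 = 2)
    expect_equal(nTracks(ts), 2L)
    nd <- trackNodes(ts)
    got1 <- nd$column[nd$track == 1]
    expect_equal(got1, c1)
    expect_equal(nd$column[nd$track == 2], c2)
    # row-pair assignments equal the exhaustive oracle
    for (r in 1:7) {
      m <- oracleRowMatch(c(c1[r], c2[r]), c(c1[r + 1], c2[r + 1]), 2)
      expect_equal(m, c(1L, 2L))
    }
  }
})

test_that("random sparse scenes link exactly as exhaustive per-row matching", {
  # <= 3 peaks/row, separations > 2 * lambda1: greedy equals optimal and
  # every ground-truth trajectory maps to exactly one track
  set.seed(32)
  lambda1 <- 2
  for (rep in 1:10) {
    n <- sample(2:3, 1)
    start <- seq(10, by = 20, length.out = n)
    steps <- matrix(sample(c(-1, 0, 1), n * 8, TRUE), 8, n)
    cols <- apply(rbind(start, steps[-1, , drop = FALSE]), 2, cumsum)
    p <- peaksFromColumns(lapply(seq_len(8), function(r) cols[r, ]))
    ts <- suppressWarnings(linkPeaks(p, lambda1 = lambda1))
    expect_equal(nTracks(ts), n)
    nd <- trackNodes(ts)
    for (j in seq_len(n)) {
      tr <- unique(nd$track[nd$column %in% cols[, j] & nd$row == 1])
      expect_equal(nd$column[nd$track == tr], unname(cols[, j]))
    }
    for (r in 1:7) {
      m <- oracleRowMatch(cols[r, ], cols[r + 1, ], lambda1)
      expect_equal(m, seq_len(n))
    }
  }
})

test_that("equidistant candidates resolve to the largest track angle", {
  # track (1,5),(2,6); candidates (3,7) and (3,5): straight continuation
  # (angle pi) beats the right-angle turn
  cand <- cbind(row = c(3, 3), column = c(7, 5))
  pick <- resolveEquidistant(c(2, 6), c(1, 5), cand)
  expect_equal(unname(cand[pick, "column"]), 7)

  # symmetric static track: equal angles -> lower column wins
  candS <- cbind(row = c(3, 3), column = c(6, 4))
  pickS <- resolveEquidistant(c(2, 5), c(1, 5), candS)
  expect_equal(unname(candS[pickS, "column"]), 4)

  # single candidate returned unchanged
  expect_equal(resolveEquidistant(c(2, 5), c(1, 5), cbind(row = 3, column = 6)), 1L)

  # 1-node track: no back-vector, lowest column with a warning
  expect_warning(pick1 <- resolveEquidistant(c(1, 5), NULL, candS),
                 "first extension")
  expect_equal(unname(candS[pick1, "column"]), 4)

  # end-to-end: the angle rule keeps a drifting track straight
  p <- peaksFromColumns(list(5, 6, c(5, 7)))
  ts <- linkPeaks(p, lambda1 = 1.5)
  nd <- trackNodes(ts)
  expect_equal(nd$column[nd$track == 1], c(5, 6, 7))
})

test_that("short-track filtering keeps exactly len > lambda2", {
  p <- peaksFromColumns(list(c(10, 30), c(10, 30), c(10, 30), 10))
  ts <- linkPeaks(p, lambda1 = 2)  # track 1: 4 nodes, track 2: 3 nodes
  expect_equal(nTracks(filterShortTracks(ts, 3)), 1L)   # 3-node removed (len <= 3)
  expect_equal(trackIds(filterShortTracks(ts, 3)), 1L)  # 4-node kept
  expect_equal(nTracks(filterShortTracks(ts, 0)), 2L)   # lambda2 = 0 keeps all
  # idempotent under re-application
  once <- filterShortTracks(ts, 3)
  expect_equal(trackNodes(filterShortTracks(once, 3)), trackNodes(once))
})

test_that("redundant-track removal applies the one-third overlap rule", {
  # two identical tracks -> exactly one survives
  tr <- data.frame(frame = 1:6, column = rep(10, 6))
  ts <- makeTracks(list(tr, tr))
  expect_equal(nTracks(removeRedundant(ts)), 1L)

  # 9-node track sharing 3 nodes with a 20-node track: 3 >= 9/3 -> removed
  long <- data.frame(frame = 1:20, column = 50)
  short <- data.frame(frame = 1:9, column = c(rep(50, 3), rep(70, 6)))
  ts2 <- removeRedundant(makeTracks(list(long, short)))
  expect_equal(nTracks(ts2), 1L)
  expect_equal(max(table(trackNodes(ts2)$track)), 20L)  # longer survives

  # sharing only 2 nodes: 2 < 9/3 -> both kept
  short2 <- data.frame(frame = 1:9, column = c(rep(50, 2), rep(70, 7)))
  expect_equal(nTracks(removeRedundant(makeTracks(list(long, short2)))), 2L)
})

test_that("branch events obey the omega windows and the Euclidean argmin", {
  # track 1 ends at (frame 10, col 20); track 2 has a node at (10, 21)
  a <- data.frame(frame = 6:10, column = c(16:19, 20))
  b <- data.frame(frame = 8:14, column = 21)
  ts <- detectBranchEvents(makeTracks(list(a, b)), omega1 = 2, omega2 = 2)
  ev <- branchEvents(ts)
  merge <- ev[ev$track == 1 & ev$direction == "merge", ]
  expect_equal(nrow(merge), 1L)
  expect_equal(merge$parent, 2L)
  expect_equal(merge$column, 21)
  expect_equal(merge$frame, 10L)

  # nearest other-track node at dframe = 3 with omega1 = 2: no event
  c2 <- data.frame(frame = 13:16, column = 20)
  ts2 <- detectBranchEvents(makeTracks(list(a, c2)), omega1 = 2, omega2 = 2)
  expect_equal(nrow(branchEvents(ts2)[branchEvents(ts2)$direction == "merge" &
                                      branchEvents(ts2)$track == 1, ]), 0L)

  # two candidates at distances sqrt(2) and 2: the sqrt(2) node wins
  d <- data.frame(frame = c(9, 10), column = c(21, 22))  # dist sqrt(2), 2
  ts3 <- detectBranchEvents(makeTracks(list(a, d)), omega1 = 2, omega2 = 2)
  ev3 <- branchEvents(ts3)
  m3 <- ev3[ev3$track == 1 & ev3$direction == "merge", ]
  expect_equal(m3$frame, 9L)
  expect_equal(m3$column, 21)

  # events satisfy their windows by construction
  set.seed(33)
  tl <- lapply(1:4, function(i)
    data.frame(frame = (1:8) + sample(0:3, 1),
               column = cumsum(c(sample(10:40, 1), sample(-1:1, 7, TRUE)))))
  tsr <- detectBranchEvents(makeTracks(tl), omega1 = 3, omega2 = 4)
  evr <- branchEvents(tsr)
  for (i in seq_len(nrow(evr))) {
    nd <- trackNodes(tsr, evr$track[i])
    endNode <- if (evr$direction[i] == "merge") nd[nrow(nd), ] else nd[1, ]
    expect_lte(abs(evr$frame[i] - endNode$frame), 3)
    expect_lte(abs(evr$column[i] - endNode$column), 4)
  }
})

test_that("a forking trajectory yields a split event near the fork frame", {
  # one trajectory splits into two at frame 6 (nucleoid-segregation style)
  before <- lapply(1:5, function(r) 30)
  after <- lapply(6:15, function(r) c(30 - (r - 5), 30 + (r - 5)))
  p <- peaksFromColumns(c(before, after))
  ts <- suppressWarnings(linkPeaks(p, lambda1 = 2))
  ts <- filterShortTracks(ts, 3)
  ts <- detectBranchEvents(ts, omega1 = 2, omega2 = 2)
  sp <- branchEvents(ts)
  sp <- sp[sp$direction == "split", ]
  expect_gte(nrow(sp), 1L)
  expect_true(any(abs(sp$frame - 6) <= 2))
})

test_that("linking invariants hold on noisy pipeline output", {
  set.seed(34)
  sc <- addGaussianNoise(generateBeadStack(walkSd = 0.5, seed = 41), 30, seed = 42)
  k <- buildKymograph(sceneStack(sc), sceneLOI(sc))
  peaks <- detectPeaks(k, segmentRows(k), "findpeaks")
  ts <- suppressWarnings(linkPeaks(peaks, lambda1 = 3))
  nd <- trackNodes(ts)
  # no peak belongs to two tracks; all nodes come from detected peaks
  expect_false(any(duplicated(nd[, c("row", "column")])))
  expect_true(all(paste(nd$row, nd$column) %in% paste(peaks$row, peaks$column)))
  # every consecutive within-track displacement <= lambda1
  for (i in unique(nd$track)) {
    d <- diff(nd$column[nd$track == i])
    if (length(d)) expect_true(all(abs(d) <= 3))
  }
})
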