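#' Per-step (instantaneous) motility statistics of a track
#'
#' For each consecutive node pair: displacement magnitude
#' |dcolumn| * pxSize, signed displacement (rightwards positive, leftwards
#' negative), time interval dframe * dt, and the corresponding
#' instantaneous and signed velocities; cumulative time adds up the
#' intervals.
#'
#' @param track data.frame of track nodes with columns \code{frame} and
#'   \code{column} (as returned by [trackNodes()]).
#' @param pxSize,dt physical calibration.
#' @return data.frame with columns \code{timeInterval}, \code{displacement},
#'   \code{signedDisplacement}, \code{instVelocity}, \code{signedVelocity},
#'   \code{cumulativeTime}; empty for a track with fewer than 2 nodes.
#' @export
instantaneousStats <- function(track, pxSize = 1, dt = 1) {
  if (nrow(track) < 2L)
    return(data.frame(timeInterval = numeric(), displacement = numeric(),
                      signedDisplacement = numeric(), instVelocity = numeric(),
                      signedVelocity = numeric(), cumulativeTime = numeric()))
  dcol <- diff(track$column) * pxSize
  dtm <- diff(track$frame) * dt
  data.frame(
    timeInterval = dtm,
    displacement = abs(dcol),
    signedDisplacement = dcol,
    instVelocity = abs(dcol) / dtm,
    signedVelocity = dcol / dtm,
    cumulativeTime = cumsum(dtm)
  )
}

#' Whole-track summary statistics
#'
#' Duration (first to last frame), speed (path length / duration), net
#' velocity (net displacement / duration), tortuosity (net displacement /
#' path length; 1 for perfectly directed motion, 0 for a path returning to
#' its start, and 0 by convention when the path length is zero), and the
#' mean and s.d. of the instantaneous velocity magnitudes.
#'
#' @inheritParams instantaneousStats
#' @return one-row data.frame: \code{duration}, \code{pathLength},
#'   \code{netDisplacement}, \code{speed}, \code{netVelocity},
#'   \code{tortuosity}, \code{meanInstVelocity}, \code{sdInstVelocity}.
#' @export
trackSummary <- function(track, pxSize = 1, dt = 1) {
  inst <- instantaneousStats(track, pxSize, dt)
  path <- sum(inst$displacement)
  net <- if (nrow(track)) abs(track$column[nrow(track)] - track$column[1L]) * pxSize else 0
  dur <- if (nrow(track)) (track$frame[nrow(track)] - track$frame[1L]) * dt else 0
  data.frame(
    duration = dur,
    pathLength = path,
    netDisplacement = net,
    speed = if (dur > 0) path / dur else 0,
    netVelocity = if (dur > 0) net / dur else 0,
    tortuosity = if (path > 0) net / path else 0,
    meanInstVelocity = if (nrow(inst)) mean(inst$instVelocity) else NA_real_,
    sdInstVelocity = if (nrow(inst) > 1L) stats::sd(inst$instVelocity) else NA_real_
  )
}

#' Classify the net direction of a track
#'
#' Sign of the net column change (last minus first node): negative is
#' leftward, positive rightward, zero stationary. An optional pause
#' threshold on the net velocity (user units) reclassifies slow tracks as
#' stationary; the default 0 keeps the strict sign rule.
#'
#' @inheritParams instantaneousStats
#' @param pauseThreshold net-velocity magnitude below or at which a track
#'   counts as stationary (default 0).
#' @return one of "left", "right", "stationary".
#' @export
classifyOrientation <- function(track, pxSize = 1, dt = 1, pauseThreshold = 0) {
  d <- track$column[nrow(track)] - track$column[1L]
  if (pauseThreshold > 0) {
    s <- trackSummary(track, pxSize, dt)
    if (s$netVelocity <= pauseThreshold) return("stationary")
  }
  if (d < 0) "left" else if (d > 0) "right" else "stationary"
}

#' Normalized intensity trace of a track
#'
#' The kymograph grey value at each node divided by the image bit depth's
#' maximum (2^bitDepth - 1), giving intensities in 0-1, together with the
#' node's time: the raw frame number and a rebased time-frame with the
#' track's first frame set to 0.
#'
#' @param track data.frame of track nodes (\code{row}, \code{frame},
#'   \code{column}).
#' @param kymo the [Kymograph-class] the track lives on.
#' @return data.frame: \code{frame}, \code{column}, \code{normIntensity},
#'   \code{normFrame}, \code{time} (normFrame * dt).
#' @export
intensityTrace <- function(track, kymo) {
  vals <- kymoValues(kymo)
  maxv <- 2^bitDepth(kymo) - 1
  j <- pmin(pmax(round(track$column), 1L), ncol(vals))
  inten <- vals[cbind(track$row, j)]
  data.frame(
    frame = track$frame,
    column = track$column,
    normIntensity = inten / maxv,
    normFrame = track$frame - track$frame[1L],
    time = (track$frame - track$frame[1L]) * frameInterval(kymo)
  )
}

freedmanDiaconisHist <- function(x) {
  # Freedman-Diaconis bin count via grDevices; unit-peak-normalized
  # frequencies at bin centers, zero-count bins excluded.
  nb <- tryCatch(grDevices::nclass.FD(x), error = function(e) NA_integer_)
  if (is.na(nb) || nb < 1L) nb <- 1L
  h <- graphics::hist(x, breaks = nb, plot = FALSE)
  keep <- h$counts > 0
  data.frame(x = h$mids[keep], y = h$counts[keep] / max(h$counts))
}

fitRsq <- function(fit, y) {
  res <- stats::resid(fit)
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(NA_real_)
  1 - sum(res^2) / tot
}

nlsSafe <- function(formula, data, start, lower = NULL) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      stats::nls(formula, data = data, start = start, algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
  fit
}

#' Fit an exponential decay to a sample distribution
#'
#' Builds the normalized frequency distribution of the samples
#' (Freedman-Diaconis bins, unit-peak normalization, zero-count bins
#' excluded) and fits y = A * exp(-x / m) by nonlinear least squares
#' (Levenberg-Marquardt, trust-region/port fallback). The fitted m is the
#' distribution's mean; used for velocity distributions and for positional
#' error distributions (where 1/b in the e^(-b x) parametrization equals
#' m). Alternatively a data.frame with columns \code{x}, \code{y} may be
#' given to fit the curve to points directly.
#'
#' @param samples numeric vector of samples (>= 5 after filtering), or a
#'   data.frame with columns \code{x}, \code{y}.
#' @param positiveOnly drop non-positive samples before binning (default
#'   TRUE, for velocity magnitudes; set FALSE for error distributions that
#'   legitimately include zero).
#' @return list of class \code{"KymoFit"}: \code{model} = "exp_decay",
#'   \code{m} (mean), \code{A}, \code{rsq}, \code{converged},
#'   \code{message}, \code{data} (the fitted points). Non-convergence and
#'   degenerate inputs are flagged, never thrown.
#' @export
fitExponentialDecay <- function(samples, positiveOnly = TRUE) {
  flagged <- function(msg) structure(
    list(model = "exp_decay", m = NA_real_, A = NA_real_, rsq = NA_real_,
         converged = FALSE, message = msg, data = NULL), class = "KymoFit")
  if (is.data.frame(samples)) {
    d <- samples
    if (!all(c("x", "y") %in% names(d))) return(flagged("need columns x and y"))
    m0 <- max(mean(d$x[d$y > max(d$y) / 2]), 1e-6)
  } else {
    s <- samples[is.finite(samples)]
    if (positiveOnly) s <- s[s > 0] else s <- s[s >= 0]
    if (length(s) < 5L) return(flagged("need at least 5 samples"))
    if (stats::sd(s) == 0) return(flagged("degenerate distribution (all samples equal)"))
    d <- freedmanDiaconisHist(s)
    if (nrow(d) < 2L) return(flagged("degenerate histogram (single occupied bin)"))
    m0 <- max(mean(s), 1e-6)
  }
  fit <- nlsSafe(y ~ A * exp(-x / m), d, start = list(A = max(d$y), m = m0))
  if (is.null(fit)) return(flagged("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["m"]]) || cf[["m"]] <= 0)
    return(flagged("fit converged to non-positive mean"))
  structure(list(model = "exp_decay", m = unname(cf[["m"]]),
                 A = unname(cf[["A"]]), rsq = fitRsq(fit, d$y),
                 converged = TRUE, message = "", data = d),
            class = "KymoFit")
}

#' Fit single-phase exponential saturation kinetics
#'
#' Fits y = a + (b - a) * (1 - exp(-c * t)) to an intensity-vs-time trace
#' by nonlinear least squares (Levenberg-Marquardt with a port-algorithm
#' fallback). a and b are the initial and plateau levels; the time constant
#' of assembly is tau = 1/c. Initial guesses: a = first value, b = last
#' value, c = 1 / (half the trace duration).
#'
#' @param trace data.frame with columns \code{time} (or \code{t}) and
#'   \code{y} (or \code{intensity}); at least 4 time points.
#' @return list of class \code{"KymoFit"}: \code{model} = "saturation",
#'   \code{a}, \code{b}, \code{c}, \code{tau} (= 1/c), \code{rsq},
#'   \code{converged}, \code{message}. A constant trace or a fit with
#'   c <= 0 is flagged, never thrown.
#' @export
fitSaturationKinetics <- function(trace) {
  flagged <- function(msg) structure(
    list(model = "saturation", a = NA_real_, b = NA_real_, c = NA_real_,
         tau = NA_real_, rsq = NA_real_, converged = FALSE, message = msg),
    class = "KymoFit")
  tcol <- intersect(c("time", "t"), names(trace))[1L]
  ycol <- intersect(c("y", "intensity"), names(trace))[1L]
  if (is.na(tcol) || is.na(ycol)) return(flagged("need columns time/t and y/intensity"))
  d <- data.frame(t = trace[[tcol]], y = trace[[ycol]])
  d <- d[is.finite(d$t) & is.finite(d$y), ]
  if (nrow(d) < 4L) return(flagged("need at least 4 time points"))
  if (stats::sd(d$y) == 0) return(flagged("constant trace (no kinetics)"))
  dur <- diff(range(d$t))
  if (dur <= 0) return(flagged("zero trace duration"))
  start <- list(a = d$y[1L], b = d$y[nrow(d)], c = 2 / dur)
  fit <- nlsSafe(y ~ a + (b - a) * (1 - exp(-c * t)), d, start = start)
  if (is.null(fit)) return(flagged("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["c"]]) || cf[["c"]] <= 0)
    return(flagged("fit converged with non-positive rate c"))
  structure(list(model = "saturation", a = unname(cf[["a"]]),
                 b = unname(cf[["b"]]), c = unname(cf[["c"]]),
                 tau = 1 / unname(cf[["c"]]), rsq = fitRsq(fit, d$y),
                 converged = TRUE, message = ""),
            class = "KymoFit")
}

#' @export
print.KymoFit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("KymoFit [%s]: not converged (%s)\n", x$model, x$message))
  } else if (x$model == "exp_decay") {
    cat(sprintf("KymoFit [exp_decay]: m = %.6g (A = %.4g, R^2 = %.4f)\n",
                x$m, x$A, x$rsq))
  } else {
    cat(sprintf("KymoFit [saturation]: tau = %.6g (a = %.4g, b = %.4g, c = %.4g, R^2 = %.4f)\n",
                x$tau, x$a, x$b, x$c, x$rsq))
  }
  invisible(x)
}
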