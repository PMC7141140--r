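# Synthetic gaze generators. Every sampling decision flows from the explicit
# `seed` argument (seed = NULL draws from the caller's RNG stream), and all
# generators emit on-screen, validation-clean sequences.

clampToScreen <- function(x, y, screen) {
  list(x = pmin(pmax(x, 0), xMax(screen)), y = pmin(pmax(y, 0), yMax(screen)))
}

#' Generate a fixation/saccade gaze sequence
#'
#' Emits \code{round(duration * rate)} samples per fixation, scattered with an
#' isotropic Gaussian of the layout's dispersion around each center, and
#' clipped to the screen. Saccades are instantaneous by default — the
#' sequence jumps from one fixation cloud to the next — which on the
#' self-similarity plot produces the classic block-diagonal structure (one
#' dark square per fixation). \code{saccadeDuration > 0} inserts linearly
#' interpolated transition samples instead.
#'
#' @param layout a \code{\link{FixationLayout}}.
#' @param screen a \code{\link{ScreenGeometry}}; all centers must lie on it.
#' @param rate sampling rate in Hz.
#' @param seed integer seed for reproducibility (\code{NULL}: current RNG
#'   stream).
#' @param saccadeDuration seconds per between-fixation transition (0 =
#'   instantaneous).
#' @return a \code{\link{GazeSequence}} with rate-synthesized timestamps.
#' @examples
#' scr <- ScreenGeometry(1000, 1000)
#' lay <- FixationLayout(rbind(c(200, 200), c(800, 700)), durations = 0.5)
#' genFixationSaccade(lay, scr, rate = 100, seed = 1)
#' @export
genFixationSaccade <- function(layout, screen, rate = 100, seed = NULL,
                               saccadeDuration = 0) {
  stopifnot(is(layout, "FixationLayout"), is(screen, "ScreenGeometry"))
  if (!isScalarNumber(rate) || rate <= 0) stopDomain("rate must be positive")
  cx <- layout@centers[, 1L]; cy <- layout@centers[, 2L]
  if (any(cx < 0 | cx > xMax(screen) | cy < 0 | cy > yMax(screen)))
    stopDomain("fixation center off screen")
  withSeed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(nrow(layout@centers))) {
      if (saccadeDuration > 0 && i > 1L) {
        nt <- round(saccadeDuration * rate)
        if (nt > 0L) {
          frac <- seq_len(nt) / (nt + 1L)
          xs <- c(xs, cx[i - 1L] + frac * (cx[i] - cx[i - 1L]))
          ys <- c(ys, cy[i - 1L] + frac * (cy[i] - cy[i - 1L]))
        }
      }
      ni <- round(layout@durations[i] * rate)
      xs <- c(xs, cx[i] + stats::rnorm(ni, 0, layout@dispersion))
      ys <- c(ys, cy[i] + stats::rnorm(ni, 0, layout@dispersion))
    }
    p <- clampToScreen(xs, ys, screen)
    GazeSequence(x = p$x, y = p$y, rate = rate)
  })
}

#' Ambient- and focal-viewing fixation layouts
#'
#' Qualitative presets for the two classic viewing styles: ambient
#' (exploratory) viewing is many short fixations scattered widely over the
#' screen, focal (inspecting) viewing is a few long fixations in one small
#' region. Centers are drawn at random within the screen's inner margin, so a
#' seed makes the layout reproducible.
#'
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param nFix number of fixations.
#' @param duration seconds per fixation.
#' @param dispersion within-fixation scatter in pixels.
#' @param seed integer seed.
#' @return a \code{\link{FixationLayout}}.
#' @export
ambientLayout <- function(screen, nFix = 20L, duration = 0.2,
                          dispersion = 15, seed = NULL) {
  withSeed(seed, {
    cx <- stats::runif(nFix, 0.05 * xMax(screen), 0.95 * xMax(screen))
    cy <- stats::runif(nFix, 0.05 * yMax(screen), 0.95 * yMax(screen))
    FixationLayout(cbind(cx, cy), durations = duration, dispersion = dispersion)
  })
}

#' @rdname ambientLayout
#' @param spread radius (pixels) of the region around the screen center that
#'   the focal fixations stay within.
#' @export
focalLayout <- function(screen, nFix = 4L, duration = 1.5, dispersion = 10,
                        spread = 0.05 * min(xMax(screen), yMax(screen)),
                        seed = NULL) {
  withSeed(seed, {
    cx <- xMax(screen) / 2 + stats::runif(nFix, -spread, spread)
    cy <- yMax(screen) / 2 + stats::runif(nFix, -spread, spread)
    FixationLayout(cbind(cx, cy), durations = duration, dispersion = dispersion)
  })
}

#' Generate a smooth-pursuit gaze sequence
#'
#' Samples lie on the piecewise-linear path through the waypoints, traversed
#' at constant speed (consecutive samples are \code{speed / rate} apart along
#' the path), with optional additive Gaussian tracking noise; the whole path
#' can be traversed several times, which shows up as dark recurrence lines
#' parallel to the diagonal of the self-similarity plot.
#'
#' @param waypoints two-column matrix of path vertices (pixels).
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param speed target speed in pixels per second.
#' @param rate sampling rate in Hz.
#' @param noise Gaussian tracking-noise standard deviation in pixels.
#' @param repeats number of path traversals.
#' @param seed integer seed.
#' @return a \code{\link{GazeSequence}}.
#' @export
genSmoothPursuit <- function(waypoints, screen, speed = 200, rate = 100,
                             noise = 0, repeats = 1L, seed = NULL) {
  waypoints <- as.matrix(waypoints)
  stopifnot(is(screen, "ScreenGeometry"), ncol(waypoints) == 2L)
  if (nrow(waypoints) < 2L) stopDomain("need at least two waypoints")
  if (!isScalarNumber(speed) || speed <= 0) stopDomain("speed must be positive")
  if (!isScalarNumber(rate) || rate <= 0) stopDomain("rate must be positive")
  segLen <- sqrt(rowSums(diff(waypoints)^2))
  total <- sum(segLen)
  if (total <= 0) stopDomain("zero-length pursuit path")
  cum <- c(0, cumsum(segLen))
  nPer <- floor(total / speed * rate) + 1L       # samples per traversal
  sAlong <- (seq_len(nPer) - 1L) * speed / rate  # arc length of each sample
  seg <- findInterval(sAlong, cum, rightmost.closed = TRUE)
  frac <- (sAlong - cum[seg]) / segLen[seg]
  px <- waypoints[seg, 1L] + frac * (waypoints[seg + 1L, 1L] - waypoints[seg, 1L])
  py <- waypoints[seg, 2L] + frac * (waypoints[seg + 1L, 2L] - waypoints[seg, 2L])
  px <- rep(px, repeats); py <- rep(py, repeats)
  withSeed(seed, {
    if (noise > 0) {
      px <- px + stats::rnorm(length(px), 0, noise)
      py <- py + stats::rnorm(length(py), 0, noise)
    }
    p <- clampToScreen(px, py, screen)
    GazeSequence(x = p$x, y = p$y, rate = rate)
  })
}

#' Generate a reading gaze sequence
#'
#' Fixates each word position of each text line in order: forward reading
#' advances left-to-right along a line, sweeps rapidly back and steps down to
#' the next line; backward reading mirrors the within-line direction. The
#' vertical position never decreases, so on the directed self-similarity plot
#' every vertical distance is non-negative — the signature the directed plot
#' makes visible for reading.
#'
#' @param layout a \code{\link{ReadingLayout}}.
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param rate sampling rate in Hz.
#' @param seed integer seed (drives the per-sample jitter).
#' @return a \code{\link{GazeSequence}}.
#' @export
genReading <- function(layout, screen, rate = 100, seed = NULL) {
  stopifnot(is(layout, "ReadingLayout"), is(screen, "ScreenGeometry"))
  if (!isScalarNumber(rate) || rate <= 0) stopDomain("rate must be positive")
  if (layout@xStart < 0 || layout@xEnd > xMax(screen) ||
      any(layout@lineY < 0) || any(layout@lineY > yMax(screen)))
    stopDomain("reading layout extends off screen")
  wordX <- seq(layout@xStart, layout@xEnd, length.out = layout@wordsPerLine)
  if (layout@direction == "backward") wordX <- rev(wordX)
  nPerWord <- max(1L, round(layout@dwell * rate))
  cx <- rep(rep(wordX, times = length(layout@lineY)), each = nPerWord)
  cy <- rep(layout@lineY, each = nPerWord * layout@wordsPerLine)
  withSeed(seed, {
    xs <- cx + stats::rnorm(length(cx), 0, layout@jitter)
    ys <- cy + stats::rnorm(length(cy), 0, layout@jitter)
    p <- clampToScreen(xs, ys, screen)
    GazeSequence(x = p$x, y = p$y, rate = rate)
  })
}

#' Inject isolated outlier samples
#'
#' Replaces \code{count} randomly chosen samples with points at least
#' \code{minOffset} pixels from the sequence centroid (drawn uniformly on the
#' screen by rejection). Outliers appear on the self-similarity plot as a
#' bright cross with a black square on the diagonal. The injected indices are
#' recorded in \code{gazeMetadata(x)$outlierIndices}.
#'
#' @param seq a \code{\link{GazeSequence}}.
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param count number of samples to replace.
#' @param minOffset minimum distance (pixels) from the sequence centroid.
#' @param seed integer seed.
#' @return the modified \code{\link{GazeSequence}}.
#' @export
injectOutliers <- function(seq, screen, count = 1L, minOffset = 200,
                           seed = NULL) {
  stopifnot(is(seq, "GazeSequence"), is(screen, "ScreenGeometry"))
  count <- as.integer(count)
  if (count < 0L || count > length(seq))
    stopDomain("count must be between 0 and the number of samples")
  if (!isScalarNumber(minOffset) || minOffset <= 0)
    stopDomain("minOffset must be positive")
  if (count == 0L) return(seq)
  ok <- gazeValid(seq)
  cx <- mean(gazeX(seq)[ok]); cy <- mean(gazeY(seq)[ok])
  corners <- rbind(c(0, 0), c(xMax(screen), 0), c(0, yMax(screen)),
                   c(xMax(screen), yMax(screen)))
  if (max(sqrt((corners[, 1L] - cx)^2 + (corners[, 2L] - cy)^2)) < minOffset)
    stopDomain("minOffset unreachable: no on-screen point is that far ",
               "from the centroid")
  withSeed(seed, {
    idx <- sample.int(length(seq), count)
    ox <- numeric(count); oy <- numeric(count)
    for (i in seq_len(count)) {
      repeat {
        px <- stats::runif(1L, 0, xMax(screen))
        py <- stats::runif(1L, 0, yMax(screen))
        if (sqrt((px - cx)^2 + (py - cy)^2) >= minOffset) break
      }
      ox[i] <- px; oy[i] <- py
    }
    x <- gazeX(seq); y <- gazeY(seq)
    x[idx] <- ox; y[idx] <- oy
    md <- gazeMetadata(seq)
    md$outlierIndices <- sort(idx)
    new("GazeSequence", t = gazeTimes(seq), x = x, y = y,
        valid = gazeValid(seq), metadata = md)
  })
}

#' Simulate movie viewing with intermittent overlay text
#'
#' Emulates a long recording of a viewer following a cartoon (smooth pursuit
#' after a wandering point) interrupted by overlay texts the viewer reads:
#' the schedule alternates pursuit breaks of 2-5 s with \code{nTexts} reading
#' segments of 7-9 s. Returns both the gaze sequence and the text-visibility
#' intervals, ready for \code{\link{metricSeries}} plus
#' \code{\link{indicatorCorrelation}}.
#'
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param rate sampling rate in Hz.
#' @param nTexts number of text presentations.
#' @param textDuration range (seconds) text durations are drawn from.
#' @param breakDuration range (seconds) between-text pursuit durations are
#'   drawn from.
#' @param pursuitSpeed wandering-point speed in pixels per second.
#' @param seed integer seed.
#' @return list with \code{gaze} (a \code{\link{GazeSequence}}) and
#'   \code{textIntervals} (data frame \code{t_start,t_end}).
#' @export
genMovieWithText <- function(screen, rate = 100, nTexts = 6L,
                             textDuration = c(7, 9), breakDuration = c(2, 5),
                             pursuitSpeed = 200, seed = NULL) {
  stopifnot(is(screen, "ScreenGeometry"))
  withSeed(seed, {
    parts <- list()
    starts <- numeric(0); ends <- numeric(0)
    tNow <- 0
    pos <- c(xMax(screen) / 2, yMax(screen) / 2)
    lineY <- seq(0.3, 0.7, length.out = 5L) * yMax(screen)
    for (k in seq_len(nTexts)) {
      # pursuit break
      durB <- stats::runif(1L, breakDuration[1L], breakDuration[2L])
      wp <- rbind(pos, cbind(
        stats::runif(4L, 0.1 * xMax(screen), 0.9 * xMax(screen)),
        stats::runif(4L, 0.1 * yMax(screen), 0.9 * yMax(screen))))
      nB <- round(durB * rate)
      seg <- genSmoothPursuit(wp, screen, speed = pursuitSpeed, rate = rate,
                              noise = 3, repeats = 1L, seed = NULL)
      if (length(seg) < nB)   # short wander: retrace the path often enough
        seg <- genSmoothPursuit(wp, screen, speed = pursuitSpeed, rate = rate,
                                noise = 3,
                                repeats = ceiling(nB / length(seg)),
                                seed = NULL)
      seg <- seg[seq_len(nB)]
      parts[[length(parts) + 1L]] <- seg
      pos <- c(gazeX(seg)[length(seg)], gazeY(seg)[length(seg)])
      tNow <- tNow + nB / rate
      # reading segment
      durT <- stats::runif(1L, textDuration[1L], textDuration[2L])
      lineTime <- 8L * 0.18                 # wordsPerLine * dwell defaults
      nLines <- max(1L, ceiling(durT / lineTime))
      lay <- ReadingLayout(sort(rep_len(lineY, nLines)),
                           xStart = 0.15 * xMax(screen),
                           xEnd = 0.85 * xMax(screen))
      txt <- genReading(lay, screen, rate = rate, seed = NULL)
      nT <- min(round(durT * rate), length(txt))
      txt <- txt[seq_len(nT)]
      parts[[length(parts) + 1L]] <- txt
      starts <- c(starts, tNow); ends <- c(ends, tNow + nT / rate)
      pos <- c(gazeX(txt)[nT], gazeY(txt)[nT])
      tNow <- tNow + nT / rate
    }
    # closing pursuit break
    durB <- stats::runif(1L, breakDuration[1L], breakDuration[2L])
    nB <- round(durB * rate)
    wp <- rbind(pos, cbind(
      stats::runif(4L, 0.1 * xMax(screen), 0.9 * xMax(screen)),
      stats::runif(4L, 0.1 * yMax(screen), 0.9 * yMax(screen))))
    seg <- genSmoothPursuit(wp, screen, speed = pursuitSpeed, rate = rate,
                            noise = 3, repeats = 1L, seed = NULL)
    if (length(seg) < nB)
      seg <- genSmoothPursuit(wp, screen, speed = pursuitSpeed, rate = rate,
                              noise = 3, repeats = ceiling(nB / length(seg)),
                              seed = NULL)
    parts[[length(parts) + 1L]] <- seg[seq_len(nB)]

    allParts <- concatGaze(parts)
    gaze <- GazeSequence(x = gazeX(allParts), y = gazeY(allParts), rate = rate)
    list(gaze = gaze,
         textIntervals = data.frame(t_start = starts, t_end = ends))
  })
}
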