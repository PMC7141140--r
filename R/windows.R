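#' Enumerate sliding windows over a gaze recording
#'
#' Windows of length \code{spec@length} start at the first timestamp and
#' advance by \code{spec@step}; a window covers the samples with
#' \eqn{t \in [start, start + length)} and the last window is the final one
#' that still fits entirely inside the recording. Long recordings (e.g. movie
#' viewing) are analysed window by window instead of through one huge
#' self-similarity matrix.
#'
#' @param seq a \code{\link{GazeSequence}} with real or rate-synthesized
#'   timestamps.
#' @param spec a \code{\link{WindowSpec}}.
#' @return data frame with one row per window: \code{start}, \code{center},
#'   \code{end} (seconds) and the 1-based sample range \code{from},
#'   \code{to} (\code{NA} for windows containing no sample). Zero rows, with
#'   a warning, when the recording is shorter than one window.
#' @examples
#' gs <- GazeSequence(x = rep(1, 500), y = rep(1, 500), rate = 100)
#' head(slidingWindows(gs, WindowSpec(1, 0.16)))
#' @export
slidingWindows <- function(seq, spec = WindowSpec()) {
  stopifnot(is(seq, "GazeSequence"), is(spec, "WindowSpec"))
  t <- gazeTimes(seq)
  if (length(t) == 0L || any(is.na(t)))
    stopDomain("sliding windows need timestamps; supply t or a sampling rate")
  t0 <- t[1L]
  dur <- t[length(t)] - t0
  eps <- 1e-9
  nWin <- floor((dur - spec@length) / spec@step + eps) + 1
  if (nWin < 1) {
    warning("recording (", signif(dur, 4), " s) is shorter than one window (",
            spec@length, " s); no windows produced", call. = FALSE)
    return(data.frame(start = numeric(0), center = numeric(0),
                      end = numeric(0), from = integer(0), to = integer(0)))
  }
  starts <- t0 + (seq_len(nWin) - 1) * spec@step
  ends <- starts + spec@length
  from <- findInterval(starts - eps, t) + 1L      # first t >= start
  to <- findInterval(ends - eps, t)               # last t < end
  # a window closing exactly at the recording end keeps the final sample
  to[ends >= t[length(t)] - eps] <- length(t)
  empty <- to < from
  from[empty] <- NA_integer_; to[empty] <- NA_integer_
  data.frame(start = starts, center = starts + spec@length / 2,
             end = ends, from = from, to = to)
}

#' Texture-metric time series over a moving window
#'
#' For each sliding window, builds the directed self-similarity matrix of the
#' window's samples and evaluates the requested texture metrics, keyed like
#' \code{"H01 contrast"} (direction, offset digits, metric; see
#' \code{\link{featureVector}}). Windows with fewer than \code{minSamples}
#' valid samples yield \code{NA} instead of failing.
#'
#' @param seq a validated \code{\link{GazeSequence}} with timestamps.
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param spec a \code{\link{WindowSpec}}.
#' @param metricKeys character vector of metric keys.
#' @param K quantization level count.
#' @param minSamples minimum samples per window (default 3).
#' @param signed signed discretization switch (see
#'   \code{\link{discretizeGSSP}}).
#' @return data frame with column \code{t} (window centers, seconds) and one
#'   column per metric key.
#' @export
metricSeries <- function(seq, screen, spec = WindowSpec(),
                         metricKeys = "H01 contrast", K = 10L,
                         minSamples = 3L, signed = FALSE) {
  stopifnot(is(seq, "GazeSequence"), is(screen, "ScreenGeometry"))
  keys <- lapply(metricKeys, parseMetricKey)  # validates early
  win <- slidingWindows(seq, spec)
  out <- matrix(NA_real_, nrow(win), length(metricKeys),
                dimnames = list(NULL, metricKeys))
  for (w in seq_len(nrow(win))) {
    if (is.na(win$from[w])) next
    slice <- seq[win$from[w]:win$to[w]]
    if (length(slice) < minSamples) next
    vh <- computeGSSPVH(slice, screen)
    d <- discretizeGSSP(vh, K = K, signed = signed)
    cms <- list()
    for (ki in seq_along(keys)) {
      k <- keys[[ki]]
      id <- paste(k$part, k$offset[1L], k$offset[2L])
      if (is.null(cms[[id]])) cms[[id]] <- cooccurrence(d, k$offset, k$part)
      cm <- cms[[id]]
      if (pairCount(cm) > 0) out[w, ki] <- metricFun(k$metric)(cm)
    }
  }
  cbind(data.frame(t = win$center), as.data.frame(out, check.names = FALSE))
}

#' Step-function task indicator from visibility intervals
#'
#' Converts a table of intervals during which a condition held (e.g. overlay
#' text visible on screen) into the 0/1 step function of time used by
#' \code{\link{indicatorCorrelation}}. Intervals are half-open
#' \eqn{[start, end)}.
#'
#' @param intervals data frame with columns \code{t_start}, \code{t_end}
#'   (seconds).
#' @return function mapping a numeric time vector to 0/1 flags.
#' @export
indicatorFunction <- function(intervals) {
  stopifnot(all(c("t_start", "t_end") %in% names(intervals)))
  if (any(intervals$t_end <= intervals$t_start))
    stopDomain("indicator intervals must satisfy t_start < t_end")
  s <- intervals$t_start; e <- intervals$t_end
  function(t) {
    flags <- vapply(t, function(ti) any(ti >= s & ti < e), logical(1L))
    as.integer(flags)
  }
}

#' Read indicator intervals from CSV
#'
#' @param path CSV with columns \code{t_start,t_end}, one row per interval.
#' @return the intervals data frame.
#' @rdname indicatorFunction
#' @export
readIndicator <- function(path) {
  if (!file.exists(path)) stop("indicator file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("t_start", "t_end") %in% names(df)))
    stopDomain("indicator file must have columns t_start,t_end")
  df
}

#' Correlate a metric series with a binary task indicator
#'
#' Samples the 0/1 indicator at the window-center times of the metric series
#' and returns the Pearson correlation between metric values and flags.
#' Missing metric values are dropped pairwise. A strong correlation ties the
#' texture metric to the task state — e.g. windowed horizontal contrast
#' rising whenever overlay text is being read.
#'
#' @param series data frame with columns \code{t} and \code{value} (or a
#'   single metric column as produced by \code{\link{metricSeries}}).
#' @param indicator an interval data frame (columns \code{t_start},
#'   \code{t_end}), or a function of time returning 0/1 flags.
#' @return Pearson correlation coefficient.
#' @export
indicatorCorrelation <- function(series, indicator) {
  stopifnot(is.data.frame(series), "t" %in% names(series))
  vcol <- setdiff(names(series), "t")
  if (length(vcol) != 1L)
    stopDomain("series must have exactly one value column besides t")
  if (length(series$t) == 0L) stopDomain("empty metric series")
  f <- if (is.function(indicator)) indicator else indicatorFunction(indicator)
  flags <- f(series$t)
  vals <- series[[vcol]]
  ok <- !is.na(vals) & !is.na(flags)
  vals <- vals[ok]; flags <- flags[ok]
  if (length(vals) < 3L) stopDomain("too few aligned points for a correlation")
  if (stats::sd(vals) == 0 || stats::sd(flags) == 0)
    stopDomain("correlation undefined: zero variance in the aligned series")
  stats::cor(vals, flags)
}
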