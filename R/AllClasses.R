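#' @import methods
NULL

# ---------------------------------------------------------------------------
# ScreenGeometry
# ---------------------------------------------------------------------------

#' Screen geometry of an eye-tracking setup
#'
#' Holds the horizontal and vertical screen extents in pixels. The diagonal
#' \code{sqrt(xMax^2 + yMax^2)} is the largest distance two on-screen gaze
#' points can have and is used to normalize all self-similarity values into
#' \eqn{[0, 1]} (see \code{\link{normalizationFactor}}).
#'
#' @slot xMax horizontal extent in pixels (positive).
#' @slot yMax vertical extent in pixels (positive).
#'
#' @examples
#' scr <- ScreenGeometry(1920, 1080)
#' normalizationFactor(scr)
#' @export
setClass("ScreenGeometry",
  representation(xMax = "numeric", yMax = "numeric"),
  validity = function(object) {
    if (!isScalarNumber(object@xMax) || !isScalarNumber(object@yMax))
      return("xMax and yMax must be single finite numbers")
    if (object@xMax <= 0 || object@yMax <= 0)
      return("screen extents must be positive")
    TRUE
  }
)

#' @param xMax,yMax screen extents in pixels.
#' @rdname ScreenGeometry-class
#' @export
ScreenGeometry <- function(xMax, yMax) new("ScreenGeometry", xMax = xMax, yMax = yMax)

#' @export
#' @describeIn ScreenGeometry-class horizontal extent in pixels.
#' @param x a \code{ScreenGeometry}.
xMax <- function(x) x@xMax

#' @export
#' @describeIn ScreenGeometry-class vertical extent in pixels.
yMax <- function(x) x@yMax

setMethod("show", "ScreenGeometry", function(object) {
  cat(sprintf("ScreenGeometry: %g x %g px (diagonal %.4f px)\n",
              object@xMax, object@yMax, sqrt(object@xMax^2 + object@yMax^2)))
})

# ---------------------------------------------------------------------------
# GazeSequence
# ---------------------------------------------------------------------------

#' Ordered raw gaze samples
#'
#' A time-ordered sequence of raw gaze samples in screen-pixel coordinates
#' (origin top-left, x rightward, y downward). Each sample carries a validity
#' flag; samples that failed numeric parsing or were flagged invalid by the
#' tracker keep their position in the sequence until
#' \code{\link{validateGaze}} resolves them. Timestamps are optional: when a
#' recording has none, a sampling rate synthesizes \code{t = (i - 1) / rate}.
#'
#' @slot t timestamps in seconds, non-decreasing over valid samples
#'   (\code{NA} when unknown).
#' @slot x,y gaze coordinates in pixels (\code{NA} allowed only on invalid
#'   samples).
#' @slot valid logical flag per sample.
#' @slot metadata free-form list (parse reports, validation logs,
#'   injected-outlier indices).
#'
#' @examples
#' gs <- GazeSequence(x = c(10, 11, 12), y = c(20, 21, 22), rate = 100)
#' length(gs)
#' as.data.frame(gs)
#' @export
setClass("GazeSequence",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 valid = "logical", metadata = "list"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@t) != n || length(object@valid) != n)
      return("t, x, y and valid must have identical length")
    if (any(is.na(object@valid)))
      return("valid flags must be TRUE or FALSE, not NA")
    bad <- object@valid & (!is.finite(object@x) | !is.finite(object@y))
    if (any(bad))
      return(sprintf("sample %d is flagged valid but has non-finite coordinates",
                     which(bad)[1L]))
    tt <- object@t[!is.na(object@t)]
    if (length(tt) > 1L && any(diff(tt) < 0))
      return("timestamps must be non-decreasing")
    TRUE
  }
)

#' @param x,y gaze coordinates in pixels.
#' @param t optional timestamps in seconds (non-decreasing).
#' @param valid optional logical validity flags (default: finite coordinates).
#' @param rate optional sampling rate in Hz used to synthesize timestamps when
#'   \code{t} is missing.
#' @param metadata optional list of provenance annotations.
#' @rdname GazeSequence-class
#' @export
GazeSequence <- function(x, y, t = NULL, valid = NULL, rate = NULL,
                         metadata = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (is.null(t)) {
    t <- if (!is.null(rate)) {
      if (!isScalarNumber(rate) || rate <= 0) stopDomain("rate must be positive")
      (seq_len(n) - 1L) / rate
    } else rep(NA_real_, n)
  }
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  new("GazeSequence", t = as.numeric(t), x = x, y = y,
      valid = as.logical(valid), metadata = metadata)
}

#' @export
#' @describeIn GazeSequence-class number of samples.
setMethod("length", "GazeSequence", function(x) length(x@x))

#' @export
#' @describeIn GazeSequence-class subset samples, preserving order.
#' @param i index vector.
setMethod("[", "GazeSequence", function(x, i, j, ..., drop = TRUE) {
  new("GazeSequence", t = x@t[i], x = x@x[i], y = x@y[i],
      valid = x@valid[i], metadata = x@metadata)
})

#' @export
#' @describeIn GazeSequence-class samples as a data frame with columns
#'   \code{t, x, y, valid}.
#' @param row.names,optional,... passed on conventionally; unused.
setMethod("as.data.frame", "GazeSequence",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(t = x@t, x = x@x, y = x@y, valid = x@valid)
  })

setMethod("show", "GazeSequence", function(object) {
  n <- length(object)
  cat(sprintf("GazeSequence: %d samples (%d invalid)", n, sum(!object@valid)))
  tt <- object@t[!is.na(object@t)]
  if (length(tt)) cat(sprintf(", t in [%.3f, %.3f] s", min(tt), max(tt)))
  cat("\n")
  if (n > 0L) {
    head <- utils::head(as.data.frame(object), 3L)
    print(head)
    if (n > 3L) cat("...\n")
  }
})

#' @export
#' @describeIn GazeSequence-class gaze timestamps in seconds.
gazeTimes <- function(x) x@t

#' @export
#' @describeIn GazeSequence-class horizontal coordinates in pixels.
gazeX <- function(x) x@x

#' @export
#' @describeIn GazeSequence-class vertical coordinates in pixels.
gazeY <- function(x) x@y

#' @export
#' @describeIn GazeSequence-class per-sample validity flags.
gazeValid <- function(x) x@valid

#' @export
#' @describeIn GazeSequence-class provenance metadata list (parse report,
#'   validation log, ...).
gazeMetadata <- function(x) x@metadata

# Concatenate sequences back-to-back. Per-part timestamps are discarded
# (each part starts at its own zero); the caller re-synthesizes a global
# clock from the sampling rate.
concatGaze <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is(parts[[1L]], "GazeSequence"))
    parts <- parts[[1L]]
  x <- unlist(lapply(parts, gazeX))
  new("GazeSequence",
      t = rep(NA_real_, length(x)),
      x = x,
      y = unlist(lapply(parts, gazeY)),
      valid = unlist(lapply(parts, gazeValid)),
      metadata = list())
}

# ---------------------------------------------------------------------------
# Matrix classes
# ---------------------------------------------------------------------------

#' Gaze self-similarity matrix
#'
#' Symmetric \eqn{n \times n} matrix of pairwise Euclidean distances between
#' gaze samples, normalized by the screen diagonal so every entry lies in
#' \eqn{[0, 1]}. Entry \eqn{(i, j)} is 0 when samples \eqn{i} and \eqn{j}
#' coincide and 1 when they sit at opposite screen corners.
#'
#' @slot values numeric matrix of normalized distances.
#' @slot screen the \code{\link{ScreenGeometry}} used for normalization.
#' @seealso \code{\link{computeGSSP}}
#' @export
setClass("GSSPMatrix",
  representation(values = "matrix", screen = "ScreenGeometry"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (nrow(v) > 0L) {
      if (any(!is.finite(v))) return("matrix entries must be finite")
      if (min(v) < -1e-9 || max(v) > 1 + 1e-9) return("entries must lie in [0, 1]")
      if (max(abs(diag(v))) > 1e-9) return("diagonal must be zero")
      if (max(abs(v - t(v))) > 1e-9) return("matrix must be symmetric")
    }
    TRUE
  }
)

#' Directed gaze self-similarity matrix
#'
#' Square matrix whose upper-right triangle stores signed horizontal distances
#' and whose lower-left triangle stores signed vertical distances between
#' temporally ordered gaze pairs, each normalized by the screen extent on its
#' axis, so entries lie in \eqn{[-1, 1]}. For the pair \eqn{(a, b)} with
#' \eqn{a < b} (sample \eqn{a} recorded first), cell \eqn{(a, b)} holds
#' \eqn{(x_b - x_a)/x_{max}} and cell \eqn{(b, a)} holds
#' \eqn{(y_b - y_a)/y_{max}}; positive values mean rightward respectively
#' downward movement.
#'
#' @slot values numeric matrix in \eqn{[-1, 1]} with zero diagonal.
#' @slot screen the \code{\link{ScreenGeometry}} used for normalization.
#' @slot convention named character vector recording which triangle stores
#'   which axis (fixed to \code{c(upper = "horizontal", lower = "vertical")}).
#' @seealso \code{\link{computeGSSPVH}}, \code{\link{reconstructScanpath}}
#' @export
setClass("DirectedGSSPMatrix",
  representation(values = "matrix", screen = "ScreenGeometry",
                 convention = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (nrow(v) > 0L) {
      if (any(!is.finite(v))) return("matrix entries must be finite")
      if (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9) return("entries must lie in [-1, 1]")
      if (max(abs(diag(v))) > 1e-9) return("diagonal must be zero")
    }
    if (!identical(unname(object@convention), c("horizontal", "vertical")) ||
        !identical(names(object@convention), c("upper", "lower")))
      return("convention must be c(upper = 'horizontal', lower = 'vertical')")
    TRUE
  }
)

#' @export
#' @describeIn GSSPMatrix-class the raw numeric matrix of a plain or directed
#'   self-similarity object.
#' @param x a \code{GSSPMatrix} or \code{DirectedGSSPMatrix}.
gsspValues <- function(x) x@values

#' @export
#' @describeIn GSSPMatrix-class screen geometry a matrix was computed against.
geometry <- function(x) x@screen

#' @export
#' @describeIn GSSPMatrix-class matrix dimensions.
setMethod("dim", "GSSPMatrix", function(x) dim(x@values))

#' @export
#' @describeIn DirectedGSSPMatrix-class matrix dimensions.
#' @param x a \code{DirectedGSSPMatrix}.
setMethod("dim", "DirectedGSSPMatrix", function(x) dim(x@values))

setMethod("show", "GSSPMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("GSSPMatrix: %d x %d, values in [%.4f, %.4f], screen %g x %g px\n",
              n, n, if (n) min(object@values) else NA, if (n) max(object@values) else NA,
              object@screen@xMax, object@screen@yMax))
})

setMethod("show", "DirectedGSSPMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf(paste0("DirectedGSSPMatrix: %d x %d, values in [%.4f, %.4f], ",
                     "upper = horizontal, lower = vertical\n"),
              n, n, if (n) min(object@values) else NA, if (n) max(object@values) else NA))
})

# ---------------------------------------------------------------------------
# Discretized / co-occurrence / rendered classes
# ---------------------------------------------------------------------------

#' Discretized self-similarity matrix
#'
#' Integer quantization of a (plain or directed) self-similarity matrix onto
#' levels \code{0..K}: level \code{floor(v * K)}, with \code{v = 1} mapping to
#' \code{K}. Directed matrices are discretized on the distance magnitude
#' \code{|v|} by default, or on the signed value via
#' \code{floor((v + 1) / 2 * K)}.
#'
#' @slot levels integer matrix with entries in \code{0..K}.
#' @slot K number of quantization levels above zero.
#' @slot signed whether the signed mapping was used.
#' @slot directed whether the source matrix was directed.
#' @seealso \code{\link{discretizeGSSP}}, \code{\link{cooccurrence}}
#' @export
setClass("DiscretizedMatrix",
  representation(levels = "matrix", K = "integer", signed = "logical",
                 directed = "logical"),
  validity = function(object) {
    if (object@K < 1L) return("K must be >= 1")
    lv <- object@levels
    if (nrow(lv) != ncol(lv)) return("levels must be square")
    if (length(lv) && (any(lv != round(lv)) || min(lv) < 0L || max(lv) > object@K))
      return("levels must be integers in 0..K")
    TRUE
  }
)

#' @export
#' @describeIn DiscretizedMatrix-class the integer level matrix.
#' @param x a \code{DiscretizedMatrix}.
levelValues <- function(x) x@levels

#' @export
#' @describeIn DiscretizedMatrix-class the quantization level count K.
levelCount <- function(x) x@K

setMethod("show", "DiscretizedMatrix", function(object) {
  cat(sprintf("DiscretizedMatrix: %d x %d, K = %d (%s%s)\n",
              nrow(object@levels), ncol(object@levels), object@K,
              if (object@directed) "directed source, " else "",
              if (object@signed) "signed mapping" else "magnitude mapping"))
})

#' Co-occurrence matrix of a discretized self-similarity plot
#'
#' \eqn{(K+1) \times (K+1)} table of how often the level pair \eqn{(a, b)}
#' occurs at a fixed cell offset \eqn{(dx, dy)} within a chosen part of the
#' discretized matrix (full matrix, strict upper "H" triangle or strict lower
#' "V" triangle). Counts are normalized by the number of counted pairs, so a
#' non-degenerate matrix sums to 1 and feeds directly into
#' \code{\link{homogeneity}}, \code{\link{contrast}} and
#' \code{\link{uniformity}}.
#'
#' @slot freq normalized pair-frequency matrix, rows = first level \code{0..K}.
#' @slot offset integer displacement \code{(dx, dy)} applied as
#'   \code{(row + dx, col + dy)}.
#' @slot part \code{"full"}, \code{"H"} or \code{"V"}.
#' @slot pairCount number of pairs counted (0 flags a degenerate matrix).
#' @slot K quantization level count of the source.
#' @export
setClass("CooccurrenceMatrix",
  representation(freq = "matrix", offset = "integer", part = "character",
                 pairCount = "numeric", K = "integer"),
  validity = function(object) {
    if (length(object@offset) != 2L) return("offset must have two components")
    if (all(object@offset == 0L)) return("offset (0,0) is not a valid displacement")
    if (!object@part %in% c("full", "H", "V")) return("part must be full, H or V")
    f <- object@freq
    if (any(dim(f) != object@K + 1L)) return("freq must be (K+1) x (K+1)")
    if (length(f) && min(f) < 0) return("frequencies must be non-negative")
    if (object@pairCount > 0 && abs(sum(f) - 1) > 1e-9)
      return("normalized frequencies must sum to 1")
    TRUE
  }
)

#' @export
#' @describeIn CooccurrenceMatrix-class the normalized pair-frequency matrix.
#' @param x a \code{CooccurrenceMatrix}.
cmFreq <- function(x) x@freq

#' @export
#' @describeIn CooccurrenceMatrix-class number of level pairs counted.
pairCount <- function(x) x@pairCount

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: K = %d, offset (%d,%d), part %s, %g pairs\n",
              object@K, object@offset[1L], object@offset[2L], object@part,
              object@pairCount))
})

#' Rendered self-similarity plot
#'
#' Raster representation of a self-similarity matrix: a grayscale intensity
#' matrix for plain matrices (0 = black = coincident gazes, 1 = white =
#' opposite corners) or an RGB array for directed matrices (red = rightward /
#' downward, green = leftward / upward, black = no displacement). Cell (1, 1)
#' renders at the upper-left, so the self-distance diagonal runs from the
#' upper-left to the lower-right corner.
#'
#' @slot pixels numeric matrix (grayscale) or H x W x 3 array (RGB), all
#'   channel values in \eqn{[0, 1]}.
#' @slot scale matrix cells per pixel along each axis (block-mean downsample
#'   factor).
#' @seealso \code{\link{renderGrayscale}}, \code{\link{renderRGB}},
#'   \code{\link{writePlotPNG}}
#' @export
setClass("RenderedPlot",
  representation(pixels = "array", scale = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!length(d) %in% c(2L, 3L)) return("pixels must be 2-d or 3-d")
    if (length(d) == 3L && d[3L] != 3L) return("color rasters must have 3 channels")
    px <- object@pixels
    if (length(px) && (min(px) < -1e-9 || max(px) > 1 + 1e-9))
      return("channel values must lie in [0, 1]")
    if (!isScalarNumber(object@scale) || object@scale < 1)
      return("scale must be a number >= 1")
    TRUE
  }
)

#' @export
#' @describeIn RenderedPlot-class the pixel array.
#' @param x a \code{RenderedPlot}.
plotPixels <- function(x) x@pixels

setMethod("show", "RenderedPlot", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RenderedPlot: %d x %d %s, %g cell(s) per pixel\n",
              d[1L], d[2L], if (length(d) == 3L) "RGB" else "grayscale",
              object@scale))
})

#' @export
#' @describeIn RenderedPlot-class draw the raster on the active graphics
#'   device.
#' @param y ignored.
#' @param ... passed to \code{\link[graphics]{rasterImage}}.
setMethod("plot", signature(x = "RenderedPlot", y = "missing"),
  function(x, y, ...) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
    graphics::rasterImage(grDevices::as.raster(x@pixels), 0, 0, 1, 1, ...)
    invisible(x)
  })

# ---------------------------------------------------------------------------
# WindowSpec
# ---------------------------------------------------------------------------

#' Moving-window specification
#'
#' Length and step of the sliding window used by \code{\link{slidingWindows}}
#' and \code{\link{metricSeries}}, both in seconds. The defaults (1 s windows
#' advanced by 0.16 s) suit long recordings such as movie viewing.
#'
#' @slot length window length in seconds (positive).
#' @slot step step between window starts in seconds (positive).
#' @export
setClass("WindowSpec",
  representation(length = "numeric", step = "numeric"),
  validity = function(object) {
    if (!isScalarNumber(object@length) || object@length <= 0)
      return("window length must be positive")
    if (!isScalarNumber(object@step) || object@step <= 0)
      return("window step must be positive")
    TRUE
  }
)

#' @param length,step window length and step in seconds.
#' @rdname WindowSpec-class
#' @export
WindowSpec <- function(length = 1.0, step = 0.16)
  new("WindowSpec", length = length, step = step)

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: length %g s, step %g s\n", object@length, object@step))
})

# ---------------------------------------------------------------------------
# Synthetic-layout classes
# ---------------------------------------------------------------------------

#' Fixation/saccade layout for synthetic gaze generation
#'
#' Describes a sequence of fixations: centers in screen pixels, a duration per
#' fixation and an isotropic Gaussian within-fixation scatter. Saccades
#' between fixations are instantaneous by default.
#'
#' @slot centers two-column matrix of fixation centers (pixels).
#' @slot durations seconds per fixation (recycled to the number of centers).
#' @slot dispersion within-fixation scatter standard deviation in pixels.
#' @seealso \code{\link{genFixationSaccade}}, \code{\link{ambientLayout}},
#'   \code{\link{focalLayout}}
#' @export
setClass("FixationLayout",
  representation(centers = "matrix", durations = "numeric",
                 dispersion = "numeric"),
  validity = function(object) {
    if (ncol(object@centers) != 2L) return("centers must be an n x 2 matrix")
    if (nrow(object@centers) < 1L) return("at least one fixation center required")
    if (length(object@durations) != nrow(object@centers))
      return("one duration per center required")
    if (any(object@durations <= 0)) return("durations must be positive")
    if (!isScalarNumber(object@dispersion) || object@dispersion < 0)
      return("dispersion must be >= 0")
    TRUE
  }
)

#' @param centers two-column matrix (or coercible) of fixation centers.
#' @param durations seconds per fixation; recycled.
#' @param dispersion scatter standard deviation in pixels.
#' @rdname FixationLayout-class
#' @export
FixationLayout <- function(centers, durations, dispersion = 10) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  new("FixationLayout", centers = centers,
      durations = rep_len(as.numeric(durations), nrow(centers)),
      dispersion = dispersion)
}

setMethod("show", "FixationLayout", function(object) {
  cat(sprintf("FixationLayout: %d fixations, total %g s, dispersion %g px\n",
              nrow(object@centers), sum(object@durations), object@dispersion))
})

#' Reading layout for synthetic gaze generation
#'
#' Describes a block of text as horizontal lines of evenly spaced word
#' positions; the generator fixates each word in order, sweeps back and steps
#' down a line. \code{direction = "backward"} mirrors the within-line order
#' (right-to-left reading with rapid left-to-right sweeps).
#'
#' @slot lineY vertical line positions in pixels, increasing.
#' @slot xStart,xEnd horizontal text extent in pixels.
#' @slot wordsPerLine number of word fixations per line.
#' @slot dwell seconds spent on each word.
#' @slot direction \code{"forward"} or \code{"backward"}.
#' @slot jitter fixation scatter standard deviation in pixels.
#' @seealso \code{\link{genReading}}
#' @export
setClass("ReadingLayout",
  representation(lineY = "numeric", xStart = "numeric", xEnd = "numeric",
                 wordsPerLine = "integer", dwell = "numeric",
                 direction = "character", jitter = "numeric"),
  validity = function(object) {
    if (length(object@lineY) < 1L) return("at least one line required")
    if (is.unsorted(object@lineY)) return("line positions must be increasing")
    if (object@xStart >= object@xEnd) return("xStart must be < xEnd")
    if (object@wordsPerLine < 2L) return("need at least two words per line")
    if (object@dwell <= 0) return("dwell must be positive")
    if (!object@direction %in% c("forward", "backward"))
      return("direction must be 'forward' or 'backward'")
    if (object@jitter < 0) return("jitter must be >= 0")
    TRUE
  }
)

#' @param lineY vertical line positions in pixels (increasing).
#' @param xStart,xEnd horizontal text extent in pixels.
#' @param wordsPerLine word fixations per line.
#' @param dwell seconds per word.
#' @param direction \code{"forward"} (left-to-right) or \code{"backward"}.
#' @param jitter fixation scatter standard deviation in pixels.
#' @rdname ReadingLayout-class
#' @export
ReadingLayout <- function(lineY, xStart, xEnd, wordsPerLine = 8L,
                          dwell = 0.18, direction = "forward", jitter = 2) {
  new("ReadingLayout", lineY = as.numeric(lineY), xStart = xStart, xEnd = xEnd,
      wordsPerLine = as.integer(wordsPerLine), dwell = dwell,
      direction = direction, jitter = jitter)
}

setMethod("show", "ReadingLayout", function(object) {
  cat(sprintf("ReadingLayout: %d lines x %d words, dwell %g s, %s\n",
              length(object@lineY), object@wordsPerLine, object@dwell,
              object@direction))
})
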