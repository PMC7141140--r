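# Block-mean downsampling: each output cell is the mean of a k x k block
# (edge blocks may be smaller).
blockMean <- function(mat, k) {
  if (k == 1L) return(mat)
  g <- ceiling(seq_len(nrow(mat)) / k)
  counts <- tabulate(g)
  sums <- rowsum(t(rowsum(mat, g)), g)  # col-block sums of row-block sums
  t(sums) / outer(counts, counts)
}

#' Render a plain self-similarity matrix in grayscale
#'
#' Maps each matrix cell to one pixel: 0 (coincident gazes) renders black and
#' 1 (opposite screen corners) renders white. Cell (1, 1) sits at the
#' upper-left, so the zero self-distance diagonal runs from the upper-left to
#' the lower-right corner; fixations appear as black diagonal squares and
#' recurrences as dark off-diagonal blocks. A downsample factor \code{k}
#' replaces each \code{k x k} cell block with its mean, keeping long
#' recordings renderable.
#'
#' @param m a \code{\link{GSSPMatrix}}.
#' @param downsample optional positive integer block size.
#' @param fixations optional fixation annotation data frame (columns
#'   \code{from}, \code{to}; see \code{\link{readFixations}}) marked as white
#'   segments on the diagonal.
#' @return a \code{\link{RenderedPlot}}.
#' @export
renderGrayscale <- function(m, downsample = NULL, fixations = NULL) {
  stopifnot(is(m, "GSSPMatrix"))
  px <- gsspValues(m)
  if (!is.null(fixations)) {
    stopifnot(all(c("from", "to") %in% names(fixations)))
    for (r in seq_len(nrow(fixations))) {
      idx <- fixations$from[r]:fixations$to[r]
      if (any(idx < 1L | idx > nrow(px)))
        stopDomain("fixation interval outside the matrix")
      px[cbind(idx, idx)] <- 1
    }
  }
  k <- checkDownsample(downsample)
  if (k > 1L) px <- blockMean(px, k)
  new("RenderedPlot", pixels = px, scale = as.numeric(k))
}

#' Render a directed self-similarity matrix in red/green
#'
#' Encodes each cell of a \code{\link{DirectedGSSPMatrix}} as a color pixel:
#' a value \eqn{v \ge 0} (rightward in the horizontal triangle, downward in
#' the vertical one) becomes \code{(R, G, B) = (v, 0, 0)} and \eqn{v < 0}
#' (leftward / upward) becomes \code{(0, -v, 0)}; zero displacement is black.
#' At full resolution no pixel carries both red and green; block-mean
#' downsampling averages each channel separately and may blend them.
#'
#' @param m a \code{\link{DirectedGSSPMatrix}}.
#' @param downsample optional positive integer block size.
#' @return a \code{\link{RenderedPlot}} with an H x W x 3 pixel array.
#' @export
renderRGB <- function(m, downsample = NULL) {
  stopifnot(is(m, "DirectedGSSPMatrix"))
  v <- gsspValues(m)
  r <- pmax(v, 0)
  g <- pmax(-v, 0)
  k <- checkDownsample(downsample)
  if (k > 1L) { r <- blockMean(r, k); g <- blockMean(g, k) }
  px <- array(0, dim = c(nrow(r), ncol(r), 3L))
  px[, , 1L] <- r
  px[, , 2L] <- g
  new("RenderedPlot", pixels = px, scale = as.numeric(k))
}

checkDownsample <- function(downsample) {
  if (is.null(downsample)) return(1L)
  k <- as.integer(downsample)
  if (is.na(k) || k < 1L) stopDomain("downsample must be a positive integer")
  k
}

#' Write a rendered plot as PNG
#'
#' Stores the raster as an 8-bit PNG (channel value \code{v} mapped to
#' \code{round(255 * v)}), written atomically.
#'
#' @param p a \code{\link{RenderedPlot}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePlotPNG <- function(p, path) {
  stopifnot(is(p, "RenderedPlot"))
  px <- pmin(pmax(p@pixels, 0), 1)
  atomicWrite(path, function(tmp) png::writePNG(px, tmp))
}
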