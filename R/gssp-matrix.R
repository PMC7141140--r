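#' Normalization factor of a screen
#'
#' The largest possible distance between two on-screen gaze points — the
#' screen diagonal \eqn{\sqrt{x_{max}^2 + y_{max}^2}} — by which all pairwise
#' gaze distances are divided so self-similarity values lie in \eqn{[0, 1]}.
#'
#' @param screen a \code{\link{ScreenGeometry}}.
#' @return positive number, in pixels.
#' @examples
#' normalizationFactor(ScreenGeometry(3, 4))  # 5
#' @export
normalizationFactor <- function(screen) {
  stopifnot(is(screen, "ScreenGeometry"))
  sqrt(xMax(screen)^2 + yMax(screen)^2)
}

checkComputable <- function(seq) {
  if (length(seq) < 1L) stopDomain("gaze sequence is empty")
  if (any(!gazeValid(seq)))
    stopDomain("sequence contains invalid samples; run validateGaze() first")
}

#' Compute the plain gaze self-similarity matrix
#'
#' Entry \eqn{(i, j)} is the Euclidean distance between gaze samples \eqn{i}
#' and \eqn{j}, divided by the screen diagonal
#' (\code{\link{normalizationFactor}}), giving a symmetric matrix with zero
#' diagonal and values in \eqn{[0, 1]}. Rendered with
#' \code{\link{renderGrayscale}}, fixations appear as dark squares on the
#' diagonal and gaze recurrences as dark off-diagonal blocks.
#'
#' @param seq a validated \code{\link{GazeSequence}} (no invalid samples).
#' @param screen the \code{\link{ScreenGeometry}} the recording was made on.
#' @return a \code{\link{GSSPMatrix}}.
#' @examples
#' scr <- ScreenGeometry(100, 100)
#' gs <- GazeSequence(x = c(0, 30, 60), y = c(0, 40, 80), rate = 100)
#' gsspValues(computeGSSP(gs, scr))
#' @export
computeGSSP <- function(seq, screen) {
  stopifnot(is(seq, "GazeSequence"), is(screen, "ScreenGeometry"))
  checkComputable(seq)
  d <- as.matrix(stats::dist(cbind(gazeX(seq), gazeY(seq)))) /
    normalizationFactor(screen)
  dimnames(d) <- NULL
  diag(d) <- 0
  new("GSSPMatrix", values = d, screen = screen)
}

#' Compute the directed (vertical/horizontal) self-similarity matrix
#'
#' For every temporally ordered pair \eqn{a < b}, the upper-right triangle
#' cell \eqn{(a, b)} stores the directed horizontal distance
#' \eqn{(x_b - x_a)/x_{max}} and the lower-left cell \eqn{(b, a)} the directed
#' vertical distance \eqn{(y_b - y_a)/y_{max}}; positive values mean movement
#' to the right respectively downwards. Unlike the plain matrix, the two
#' triangles are not redundant mirrors, and the full scan-path can be
#' recovered from the matrix plus a single anchored point
#' (\code{\link{reconstructScanpath}}).
#'
#' @inheritParams computeGSSP
#' @return a \code{\link{DirectedGSSPMatrix}}.
#' @export
computeGSSPVH <- function(seq, screen) {
  stopifnot(is(seq, "GazeSequence"), is(screen, "ScreenGeometry"))
  checkComputable(seq)
  x <- gazeX(seq); y <- gazeY(seq)
  # dx[i, j] = (x_j - x_i) / xMax ; dy[i, j] = (y_i - y_j) / yMax
  dxU <- -outer(x, x, "-") / xMax(screen)
  dyL <- outer(y, y, "-") / yMax(screen)
  v <- matrix(0, length(x), length(x))
  up <- upper.tri(v)
  v[up] <- dxU[up]
  lo <- lower.tri(v)
  v[lo] <- dyL[lo]
  new("DirectedGSSPMatrix", values = v, screen = screen,
      convention = c(upper = "horizontal", lower = "vertical"))
}

#' Reconstruct a scan-path from a directed self-similarity matrix
#'
#' A \code{\link{DirectedGSSPMatrix}} stores every pairwise displacement along
#' both axes, so knowing the absolute position of any one gaze point fixes
#' all the others: the stored normalized distances are rescaled by
#' \eqn{x_{max}} (horizontal triangle) and \eqn{y_{max}} (vertical triangle)
#' and added to, or subtracted from, the anchor's coordinates depending on the
#' temporal order of each pair relative to the anchor.
#'
#' @param m a \code{\link{DirectedGSSPMatrix}}.
#' @param anchorIndex 1-based index of the known gaze sample.
#' @param anchorPoint numeric \code{c(x, y)} absolute position of that sample
#'   in pixels.
#' @param screen the \code{\link{ScreenGeometry}}; defaults to the matrix's
#'   own provenance.
#' @return a \code{\link{GazeSequence}} of absolute positions (timestamps
#'   unknown, hence \code{NA}) whose \code{\link{computeGSSPVH}} reproduces
#'   \code{m}.
#' @examples
#' scr <- ScreenGeometry(100, 100)
#' gs <- GazeSequence(x = c(10, 40, 40), y = c(20, 20, 70))
#' m <- computeGSSPVH(gs, scr)
#' rec <- reconstructScanpath(m, 1, c(10, 20))
#' all.equal(gazeX(rec), gazeX(gs))
#' @export
reconstructScanpath <- function(m, anchorIndex, anchorPoint, screen = geometry(m)) {
  stopifnot(is(m, "DirectedGSSPMatrix"))
  v <- gsspValues(m)
  n <- nrow(v)
  if (n < 1L) stopDomain("empty matrix")
  s <- as.integer(anchorIndex)
  if (is.na(s) || s < 1L || s > n)
    stop("anchorIndex must be in 1..", n, call. = FALSE)
  if (length(anchorPoint) != 2L || !all(is.finite(anchorPoint)))
    stopDomain("anchorPoint must be finite c(x, y)")

  x <- numeric(n); y <- numeric(n)
  x[s] <- anchorPoint[1L]; y[s] <- anchorPoint[2L]
  later <- seq_len(n) > s
  earlier <- seq_len(n) < s
  # upper triangle holds (x_b - x_a)/xMax for a < b
  x[later]   <- x[s] + v[s, later] * xMax(screen)
  x[earlier] <- x[s] - v[earlier, s] * xMax(screen)
  # lower triangle holds (y_b - y_a)/yMax for a < b
  y[later]   <- y[s] + v[later, s] * yMax(screen)
  y[earlier] <- y[s] - v[s, earlier] * yMax(screen)
  GazeSequence(x = x, y = y)
}

#' Write / read a self-similarity matrix as dense CSV
#'
#' \code{writeGSSPMatrix} exports the raw values as a dense, headerless CSV
#' (one matrix row per line). \code{readGSSPMatrix} reads such a file back;
#' because the CSV does not carry provenance, the screen geometry and matrix
#' type (\code{"plain"} symmetric or \code{"vh"} directed) must be restated.
#'
#' @param m a \code{\link{GSSPMatrix}} or \code{\link{DirectedGSSPMatrix}}.
#' @param path CSV path.
#' @return \code{writeGSSPMatrix}: the path, invisibly; \code{readGSSPMatrix}:
#'   the reconstructed matrix object.
#' @export
writeGSSPMatrix <- function(m, path) {
  stopifnot(is(m, "GSSPMatrix") || is(m, "DirectedGSSPMatrix"))
  atomicWrite(path, function(tmp)
    data.table::fwrite(as.data.frame(gsspValues(m)), tmp, col.names = FALSE))
}

#' @param type \code{"plain"} or \code{"vh"}.
#' @param screen the \code{\link{ScreenGeometry}} the matrix was computed
#'   against (defaults to a unit square when only rendering is intended).
#' @rdname writeGSSPMatrix
#' @export
readGSSPMatrix <- function(path, type = c("plain", "vh"), screen = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  v <- as.matrix(data.table::fread(path, header = FALSE, data.table = FALSE))
  dimnames(v) <- NULL
  if (is.null(screen)) screen <- ScreenGeometry(1, 1)
  if (type == "plain") new("GSSPMatrix", values = v, screen = screen)
  else new("DirectedGSSPMatrix", values = v, screen = screen,
           convention = c(upper = "horizontal", lower = "vertical"))
}
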