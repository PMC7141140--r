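#' Discretize a self-similarity matrix to K levels
#'
#' Quantizes continuous self-similarity values onto the integer levels
#' \code{0..K} via \code{floor(v * K)}, with \code{v = 1} mapping to the top
#' level \code{K}. This is the prerequisite for building a co-occurrence
#' matrix, whose size equals the number of distinct values. Plain matrices
#' (values in \eqn{[0, 1]}) are quantized directly; directed matrices (values
#' in \eqn{[-1, 1]}) are quantized on the distance magnitude \code{|v|} by
#' default, or — with \code{signed = TRUE} — on the signed value via
#' \code{floor((v + 1) / 2 * K)} so that direction information survives.
#'
#' @param m a \code{\link{GSSPMatrix}} or \code{\link{DirectedGSSPMatrix}}.
#' @param K number of levels above zero (default 10).
#' @param signed for directed matrices only: use the signed mapping.
#' @return a \code{\link{DiscretizedMatrix}}.
#' @examples
#' scr <- ScreenGeometry(100, 100)
#' gs <- GazeSequence(x = c(0, 30, 60), y = c(0, 40, 80))
#' levelValues(discretizeGSSP(computeGSSP(gs, scr), K = 10))
#' @export
setGeneric("discretizeGSSP", function(m, K = 10L, signed = FALSE)
  standardGeneric("discretizeGSSP"))

quantize01 <- function(v, K) {
  lv <- floor(v * K)
  lv[lv > K] <- K  # v == 1 (and fp dust above it) maps to the top level
  lv[lv < 0L] <- 0L
  storage.mode(lv) <- "integer"
  lv
}

#' @rdname discretizeGSSP
setMethod("discretizeGSSP", "GSSPMatrix", function(m, K = 10L, signed = FALSE) {
  K <- checkK(K)
  new("DiscretizedMatrix", levels = quantize01(gsspValues(m), K), K = K,
      signed = FALSE, directed = FALSE)
})

#' @rdname discretizeGSSP
setMethod("discretizeGSSP", "DirectedGSSPMatrix",
  function(m, K = 10L, signed = FALSE) {
    K <- checkK(K)
    v <- gsspValues(m)
    lv <- if (signed) quantize01((v + 1) / 2, K) else quantize01(abs(v), K)
    new("DiscretizedMatrix", levels = lv, K = K, signed = signed,
        directed = TRUE)
  })

checkK <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stopDomain("K must be a positive integer")
  K
}

#' Co-occurrence matrix of a discretized self-similarity plot
#'
#' Counts, over a chosen part of the discretized matrix, how often the level
#' pair \eqn{(a, b)} occurs at cell positions \eqn{p} and \eqn{p + (dx, dy)}
#' (offset applied as \code{(row + dx, col + dy)}). For directed matrices the
#' two triangles describe different movement axes, so the count domain can be
#' restricted to the strict upper triangle (\code{part = "H"}, horizontal
#' distances) or the strict lower triangle (\code{part = "V"}, vertical
#' distances); \code{part = "full"} uses every cell including the diagonal.
#' Pairs whose partner falls outside the domain are skipped, and counts are
#' normalized by the number counted so the result sums to 1.
#'
#' @param d a \code{\link{DiscretizedMatrix}}.
#' @param offset integer \code{c(dx, dy)} displacement, not \code{c(0, 0)}.
#' @param part \code{"full"}, \code{"H"} or \code{"V"}.
#' @return a \code{\link{CooccurrenceMatrix}}; when no pair fits the domain
#'   (e.g. a 1 x 1 matrix) the result is degenerate with \code{pairCount} 0.
#' @export
cooccurrence <- function(d, offset = c(0L, 1L), part = c("full", "H", "V")) {
  stopifnot(is(d, "DiscretizedMatrix"))
  part <- match.arg(part)
  offset <- as.integer(offset)
  if (length(offset) != 2L || any(is.na(offset)))
    stopDomain("offset must be integer c(dx, dy)")
  if (all(offset == 0L)) stopDomain("offset (0,0) is not a valid displacement")
  lv <- levelValues(d)
  K <- levelCount(d)
  n <- nrow(lv)

  pos <- domainIndices(n, part)
  r2 <- pos$r + offset[1L]
  c2 <- pos$c + offset[2L]
  keep <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= n
  keep <- keep & switch(part,
    full = TRUE,
    H = r2 < c2,
    V = r2 > c2)
  npair <- sum(keep)
  freq <- matrix(0, K + 1L, K + 1L)
  if (npair > 0L) {
    a <- lv[cbind(pos$r[keep], pos$c[keep])]
    b <- lv[cbind(r2[keep], c2[keep])]
    counts <- tabulate(a * (K + 1L) + b + 1L, nbins = (K + 1L)^2)
    freq <- matrix(counts, K + 1L, K + 1L, byrow = TRUE) / npair
  }
  new("CooccurrenceMatrix", freq = freq, offset = offset, part = part,
      pairCount = as.numeric(npair), K = K)
}

domainIndices <- function(n, part) {
  if (n == 0L) return(list(r = integer(0), c = integer(0)))
  if (part == "full") {
    list(r = rep.int(seq_len(n), n), c = rep(seq_len(n), each = n))
  } else {
    which_tri <- if (part == "H") upper.tri(diag(n)) else lower.tri(diag(n))
    idx <- which(which_tri)
    list(r = ((idx - 1L) %% n) + 1L, c = ((idx - 1L) %/% n) + 1L)
  }
}

checkCM <- function(cm) {
  stopifnot(is(cm, "CooccurrenceMatrix"))
  if (pairCount(cm) == 0)
    stopDomain("degenerate co-occurrence matrix (no counted pairs); ",
               "texture metrics are undefined")
}

#' Texture metrics of a co-occurrence matrix
#'
#' Classic co-occurrence texture statistics applied to the self-similarity
#' plot, with level indices \eqn{i, j = 0..K} and normalized frequencies
#' \eqn{cm(i, j)}:
#' \describe{
#'   \item{\code{homogeneity}}{\eqn{\sum_{i,j} cm(i,j) / (1 + |i - j|)}, in
#'     \eqn{[0, 1]}; high when mass concentrates near the diagonal (nearby
#'     gazes at similar distances), exactly 1 for a constant image.}
#'   \item{\code{contrast}}{\eqn{\sum_{i,j} (i - j)^2 cm(i,j)}, in
#'     \eqn{[0, K^2]}; the difference moment, sensitive to long jumps from
#'     one gaze point to another, 0 for a constant image and inversely
#'     related to homogeneity.}
#'   \item{\code{uniformity}}{(also called energy)
#'     \eqn{\sum_{i,j} cm(i,j)^2}, in \eqn{[0, 1]}; high when the same paired
#'     values repeat throughout the image, 1 for a constant image.}
#' }
#'
#' @param cm a non-degenerate \code{\link{CooccurrenceMatrix}}.
#' @return a single number.
#' @examples
#' scr <- ScreenGeometry(1000, 1000)
#' gs <- GazeSequence(x = rep(500, 20), y = rep(500, 20))
#' cm <- cooccurrence(discretizeGSSP(computeGSSP(gs, scr)), c(0, 1))
#' c(homogeneity(cm), contrast(cm), uniformity(cm))
#' @export
homogeneity <- function(cm) {
  checkCM(cm)
  K <- cm@K
  w <- 1 / (1 + abs(outer(0:K, 0:K, "-")))
  sum(cmFreq(cm) * w)
}

#' @rdname homogeneity
#' @export
contrast <- function(cm) {
  checkCM(cm)
  K <- cm@K
  w <- outer(0:K, 0:K, "-")^2
  sum(cmFreq(cm) * w)
}

#' @rdname homogeneity
#' @export
uniformity <- function(cm) {
  checkCM(cm)
  sum(cmFreq(cm)^2)
}

metricFun <- function(name) switch(name,
  homogeneity = homogeneity, contrast = contrast, uniformity = uniformity,
  stopDomain("unknown metric: ", name))

featureKey <- function(part, offset, metric)
  sprintf("%s%d%d %s", part, offset[1L], offset[2L], metric)

# "H11 contrast" or "H11-contrast" -> list(part, offset, metric)
parseMetricKey <- function(key) {
  m <- regmatches(key, regexec("^([HV])([0-9])([0-9])[ -](\\w+)$", key))[[1L]]
  if (length(m) != 5L || !m[5L] %in% c("contrast", "homogeneity", "uniformity"))
    stopDomain("cannot parse metric key: '", key,
               "' (expected e.g. 'H11 contrast')")
  list(part = m[2L], offset = c(as.integer(m[3L]), as.integer(m[4L])),
       metric = m[5L])
}

#' Texture feature vector of a directed self-similarity matrix
#'
#' Evaluates contrast, homogeneity and uniformity separately for the
#' horizontal (upper-right) and vertical (lower-left) triangles and for each
#' requested offset. With the defaults — K = 10 levels and offsets (0,1),
#' (1,0) and (1,1) — this yields 18 named attributes per observation, keyed
#' like \code{"H01 contrast"} (direction, offset digits, metric). Features
#' whose offset admits no pair in the triangle are returned as \code{NA}.
#'
#' @param m a \code{\link{DirectedGSSPMatrix}}.
#' @param K quantization level count.
#' @param offsets list of integer \code{c(dx, dy)} offsets.
#' @param signed use the signed discretization (see
#'   \code{\link{discretizeGSSP}}).
#' @return named numeric vector, one value per (direction, offset, metric).
#' @export
featureVector <- function(m, K = 10L,
                          offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L)),
                          signed = FALSE) {
  stopifnot(is(m, "DirectedGSSPMatrix"))
  d <- discretizeGSSP(m, K = K, signed = signed)
  metrics <- c("contrast", "homogeneity", "uniformity")
  out <- numeric(0)
  for (part in c("H", "V")) {
    for (off in offsets) {
      cm <- cooccurrence(d, offset = off, part = part)
      for (met in metrics) {
        val <- if (pairCount(cm) > 0) metricFun(met)(cm) else NA_real_
        out[featureKey(part, off, met)] <- val
      }
    }
  }
  out
}

#' Report and prune highly correlated features
#'
#' Across a table of feature vectors (one row per observation), features of
#' the same direction and metric computed at different offsets are often
#' nearly collinear; this reports every such pair whose absolute Pearson
#' correlation exceeds \code{threshold} and removes a configured drop list.
#' The default drop list removes uniformity at offsets (0,1) and (1,0) in
#' both directions, reducing the default 18 attributes to 14.
#'
#' @param features matrix or data frame, columns named by feature key (as
#'   produced by \code{\link{featureVector}}), at least 3 rows.
#' @param threshold correlation bound in (0, 1].
#' @param drop character vector of feature keys to remove; \code{NULL} uses
#'   the default uniformity drop list.
#' @return list with \code{keep} (retained keys), \code{dropped} and
#'   \code{report} (data frame of compared pairs with their correlation;
#'   \code{r} is \code{NA} when a column has zero variance).
#' @export
pruneCorrelated <- function(features, threshold = 0.9, drop = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 3L)
    stopDomain("need at least 3 observations to assess correlations")
  if (!isScalarNumber(threshold) || threshold <= 0 || threshold > 1)
    stopDomain("threshold must be in (0, 1]")
  keys <- colnames(features)
  if (is.null(keys)) stopDomain("feature columns must be named")
  parsed <- lapply(keys, parseMetricKey)
  dir <- vapply(parsed, `[[`, "", "part")
  met <- vapply(parsed, `[[`, "", "metric")

  rows <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (j <= i || dir[i] != dir[j] || met[i] != met[j]) next
      xi <- features[, i]; xj <- features[, j]
      r <- if (stats::sd(xi, na.rm = TRUE) == 0 ||
               stats::sd(xj, na.rm = TRUE) == 0) NA_real_
           else stats::cor(xi, xj, use = "complete.obs")
      rows[[length(rows) + 1L]] <- data.frame(
        key1 = keys[i], key2 = keys[j], r = r,
        flagged = !is.na(r) && abs(r) > threshold)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(key1 = character(0), key2 = character(0),
                            r = numeric(0), flagged = logical(0))
  if (is.null(drop))
    drop <- c("H01 uniformity", "H10 uniformity",
              "V01 uniformity", "V10 uniformity")
  drop <- intersect(drop, keys)
  list(keep = setdiff(keys, drop), dropped = drop, report = report)
}

#' Write a feature table as CSV or JSON
#'
#' One row per observation, columns named by feature key.
#'
#' @param features matrix or data frame of feature vectors.
#' @param path output path; a \code{.json} extension selects JSON, anything
#'   else CSV.
#' @return the path, invisibly.
#' @export
writeFeatures <- function(features, path) {
  df <- as.data.frame(as.matrix(features))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    atomicWrite(path, function(tmp)
      jsonlite::write_json(df, tmp, digits = NA, dataframe = "rows"))
  } else {
    atomicWrite(path, function(tmp) data.table::fwrite(df, tmp))
  }
}
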