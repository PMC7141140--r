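#' Read a raw gaze recording from delimited text
#'
#' Reads one gaze sample per row from a CSV/TSV file. Rows whose mapped
#' coordinate fields fail numeric parsing are kept in place and flagged
#' invalid rather than dropped, so sample indices stay aligned with the file;
#' the counts are available afterwards via
#' \code{gazeMetadata(x)$parseReport}.
#'
#' @param path path to the delimited text file.
#' @param columns named vector mapping the roles \code{t}, \code{x}, \code{y}
#'   and optionally \code{valid} to column names (character) or 1-based column
#'   indices (numeric). \code{t} and \code{valid} may be omitted.
#' @param delim field delimiter.
#' @param header whether the file has a header row; \code{NA} (default) lets
#'   \code{\link[data.table]{fread}} auto-detect.
#' @param rate optional sampling rate in Hz used to synthesize timestamps when
#'   no \code{t} column is mapped.
#' @return a \code{\link{GazeSequence}} in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t,x,y", "0,10,20", "0.01,11,21", "0.02,12,22"), f)
#' readGaze(f)
#' @export
readGaze <- function(path, columns = c(t = "t", x = "x", y = "y"),
                     delim = ",", header = NA, rate = NULL) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  roles <- names(columns)
  if (is.null(roles) || !all(c("x", "y") %in% roles))
    stopDomain("`columns` must at least map roles 'x' and 'y'")
  if (anyDuplicated(roles))
    stopDomain("duplicate role in column mapping: ",
               roles[duplicated(roles)][1L])
  if (anyDuplicated(columns))
    stopDomain("two roles mapped to the same column: ",
               columns[duplicated(columns)][1L])

  dt <- data.table::fread(path, sep = delim, header = header,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0L) stopDomain("gaze file contains no data rows: ", path)

  pick <- function(role) {
    if (!role %in% roles) return(NULL)
    key <- columns[[role]]
    idx <- suppressWarnings(as.integer(key))
    if (!is.na(idx) && !key %in% names(dt)) {
      if (idx < 1L || idx > ncol(dt))
        stopDomain("column index out of range for role '", role, "': ", key)
      return(dt[[idx]])
    }
    if (!key %in% names(dt))
      stopDomain("mapped column not found for role '", role, "': ", key)
    dt[[key]]
  }

  num <- function(v) if (is.null(v)) NULL else suppressWarnings(as.numeric(v))
  x <- num(pick("x")); y <- num(pick("y")); t <- num(pick("t"))
  vraw <- pick("valid")
  valid <- is.finite(x) & is.finite(y)
  if (!is.null(vraw)) {
    flag <- tolower(trimws(vraw)) %in% c("1", "true", "t", "yes")
    valid <- valid & flag
  }
  if (!any(valid)) stopDomain("no parsable gaze rows in: ", path)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_

  GazeSequence(x = x, y = y, t = t, valid = valid, rate = rate,
               metadata = list(parseReport = list(
                 total = nrow(dt), invalid = sum(!valid), source = path)))
}

#' Write a gaze sequence as CSV
#'
#' Emits one sample per row with header \code{t,x,y,valid}. Reading the file
#' back with \code{\link{readGaze}} reproduces the valid samples exactly (up
#' to numeric formatting).
#'
#' @param seq a \code{\link{GazeSequence}}.
#' @param path output path; written atomically.
#' @return the path, invisibly.
#' @export
writeGaze <- function(seq, path) {
  stopifnot(is(seq, "GazeSequence"))
  df <- as.data.frame(seq)
  df$valid <- as.integer(df$valid)
  atomicWrite(path, function(tmp)
    data.table::fwrite(df, tmp, na = "NA"))
}

#' Validate a gaze sequence against a screen geometry
#'
#' Resolves invalid samples (failed parses, tracker dropouts) and off-screen
#' coordinates. \code{policy = "drop"} removes offending samples and logs the
#' count in \code{gazeMetadata(x)$validation}; \code{"clamp"} clips finite
#' off-screen coordinates into \eqn{[0, x_{max}] \times [0, y_{max}]} (samples
#' without finite coordinates are still dropped); \code{"error"} raises on the
#' first offending sample. The operation is idempotent under every policy.
#'
#' @param seq a \code{\link{GazeSequence}}.
#' @param screen a \code{\link{ScreenGeometry}}.
#' @param policy \code{"drop"}, \code{"clamp"} or \code{"error"}.
#' @return a validated \code{\link{GazeSequence}} whose valid samples all lie
#'   on screen, in the original order.
#' @export
validateGaze <- function(seq, screen, policy = c("drop", "clamp", "error")) {
  stopifnot(is(seq, "GazeSequence"), is(screen, "ScreenGeometry"))
  policy <- match.arg(policy)
  x <- gazeX(seq); y <- gazeY(seq)
  finite <- is.finite(x) & is.finite(y)
  onScreen <- finite & x >= 0 & x <= xMax(screen) & y >= 0 & y <= yMax(screen)
  ok <- gazeValid(seq) & onScreen

  if (policy == "error") {
    if (!all(ok))
      stopDomain("sample ", which(!ok)[1L],
                 " is invalid or off-screen (policy = 'error')")
    return(seq)
  }
  if (policy == "clamp") {
    keep <- gazeValid(seq) & finite
    x2 <- pmin(pmax(x[keep], 0), xMax(screen))
    y2 <- pmin(pmax(y[keep], 0), yMax(screen))
    md <- gazeMetadata(seq)
    md$validation <- list(policy = "clamp", removed = sum(!keep),
                          clamped = sum(x2 != x[keep] | y2 != y[keep]))
    return(new("GazeSequence", t = gazeTimes(seq)[keep], x = x2, y = y2,
               valid = rep(TRUE, sum(keep)), metadata = md))
  }
  # drop
  md <- gazeMetadata(seq)
  md$validation <- list(policy = "drop", removed = sum(!ok))
  new("GazeSequence", t = gazeTimes(seq)[ok], x = x[ok], y = y[ok],
      valid = rep(TRUE, sum(ok)), metadata = md)
}

#' Read fixation annotations
#'
#' Reads externally detected fixation intervals from a CSV with columns
#' \code{start_index,end_index,label}. On disk the intervals are 0-based and
#' half-open (start inclusive, end exclusive); the returned data frame
#' converts them to 1-based inclusive sample ranges (\code{from}, \code{to})
#' ready for subsetting a \code{\link{GazeSequence}} or overlaying on a
#' rendered plot.
#'
#' @param path CSV path.
#' @param n optional sequence length used to check interval bounds.
#' @return data frame with columns \code{from}, \code{to}, \code{label}.
#' @seealso \code{\link{renderGrayscale}} for the diagonal overlay.
#' @export
readFixations <- function(path, n = NULL) {
  if (!file.exists(path)) stop("fixation file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("start_index", "end_index")
  if (!all(need %in% names(df)))
    stopDomain("fixation file must have columns start_index,end_index[,label]")
  s <- as.integer(df$start_index); e <- as.integer(df$end_index)
  if (any(is.na(s) | is.na(e)) || any(s < 0L) || any(e <= s))
    stopDomain("fixation intervals must satisfy 0 <= start_index < end_index")
  if (!is.null(n) && any(e > n))
    stopDomain("fixation interval ends beyond sequence length ", n)
  data.frame(from = s + 1L, to = e,
             label = if ("label" %in% names(df)) as.character(df$label)
                     else rep("", length(s)))
}
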