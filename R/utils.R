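# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Write via a temp file in the target directory, then rename: consumers never
# observe a partially written output.
atomicWrite <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir, call. = FALSE)
  tmp <- tempfile(pattern = ".gssp-", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

stopDomain <- function(...) stop(..., call. = FALSE)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
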