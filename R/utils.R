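#' @keywords internal
"_PACKAGE"

#' @import methods
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a per-component substream seed from a base seed; keeps results for
## component i unchanged when further components are added.
substream_seed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 97 +
              as.numeric(index)) %% 2147483647)
}

## Strip EBImage's Image class, returning a plain base matrix.
as_mat <- function(img) {
  d <- dim(img)
  matrix(as.numeric(EBImage::imageData(img)), d[1L], d[2L])
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

## Maximal runs of TRUE in a logical vector as an inclusive (start, end) table.
runs_true <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

## Row-major argmax (lowest row, then lowest column) over a set of pixels.
## `y`, `x`: pixel coordinates; `v`: their values. Returns the index into y/x.
argmax_rowmajor <- function(v, y, x) {
  order(-v, y, x)[1L]
}
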