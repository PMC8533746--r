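# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL runs expr unseeded.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed) || abs(seed) >= 2^31) {
    stop("seed must fit a 32-bit integer")
  }
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# Continuous-coordinate convention: pixel i (1-based) of a grid with origin o
# and pixel size s covers [o + (i-1)*s, o + i*s), center at o + (i - 0.5)*s.
.pixelCenters <- function(n, origin, pixelSize) {
  origin + (seq_len(n) - 0.5) * pixelSize
}

.gridOrigin <- function(grid) {
  o <- attr(grid, "origin")
  if (is.null(o)) c(0, 0) else o
}

.gridPixelSize <- function(grid, default = NULL) {
  s <- attr(grid, "pixelSize")
  if (is.null(s)) default else s
}
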