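#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Row-wise z-scoring with the sample (n-1) standard deviation.
## Zero-variance rows become all-zero; their indices are returned as an
## attribute "constant_rows" so callers can flag or drop them.
zscore_rows <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  centred <- x - mu
  sd <- sqrt(rowSums(centred^2) / max(1L, ncol(x) - 1L))
  constant <- which(sd < tol)
  sd[sd < tol] <- 1
  z <- centred / sd
  z[constant, ] <- 0
  attr(z, "constant_rows") <- constant
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
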