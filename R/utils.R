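# Internal helpers shared across modules.

nif_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "nif_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the prior
#' RNG state so library callers never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  code
}

# Row-major (last axis fastest) flattening of an R array; R stores arrays
# column-major, so the axis order is reversed before vectorizing.
flatten_rm <- function(a) {
  d <- dim(a)
  if (is.null(d) || length(d) == 1L) return(as.vector(a))
  as.vector(aperm(a, rev(seq_along(d))))
}

unflatten_rm <- function(v, shape) {
  if (length(shape) == 1L) return(array(v, dim = shape))
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

# Deterministic matrix product: accumulates rank-1 terms in a fixed k order so
# each output row is computed independently of how many rows are requested.
# BLAS gemm does not guarantee this (its blocking depends on the row count),
# which would break the decoder's bit-exact ROI/full consistency contract.
mm_det <- function(a, b) {
  n <- nrow(a)
  m <- ncol(b)
  out <- matrix(0, n, m)
  for (k in seq_len(ncol(a))) {
    out <- out + outer(a[, k], b[k, ])
  }
  out
}

# 0-based multi-indices (row-major order) for flat positions `p0` (0-based)
# within `shape`. Returns a length(p0) x length(shape) matrix.
flat_to_multi <- function(p0, shape) {
  d <- length(shape)
  out <- matrix(0, length(p0), d)
  rem <- as.numeric(p0)
  for (ax in seq_len(d)) {
    stride <- prod(shape[seq_len(d)[-seq_len(ax)]])
    if (ax == d) stride <- 1
    out[, ax] <- floor(rem / stride)
    rem <- rem - out[, ax] * stride
  }
  out
}

multi_to_flat <- function(idx, shape) {
  d <- length(shape)
  strides <- rev(cumprod(rev(c(shape[-1], 1))))
  as.numeric(idx %*% strides)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
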