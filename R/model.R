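# Sinusoidal coordinate MLP (SIREN) with per-layer learnable frequencies.
#
# "depth" counts weight layers. For depth >= 3, layers 1..depth-1 are sine
# layers (layer 1: in_dim -> width, layers 2..depth-1: width -> width) and
# layer `depth` is a linear head (width -> out_dim). Each sine layer l
# computes sin(omega_l * (W_l x + b_l)) with its own trainable scalar
# frequency omega_l. depth == 2 degenerates to a single affine map
# in_dim -> out_dim with no sine layer and no frequencies.

layer_dims <- function(in_dim, out_dim, width, depth) {
  if (depth < 2) nif_stop("depth must be >= 2", "nif_error_arch")
  if (depth == 2) return(list(ins = in_dim, outs = out_dim))
  ins <- c(in_dim, rep(width, depth - 1L))
  outs <- c(rep(width, depth - 1L), out_dim)
  list(ins = ins, outs = outs)
}

#' Initialize a sinusoidal coordinate network
#'
#' First-layer weights are drawn uniform on `[-1/in_dim, 1/in_dim]`; deeper
#' layers uniform on `[-sqrt(6/fan_in)/omega0, sqrt(6/fan_in)/omega0]`
#' (the standard SIREN scheme). Biases start at zero and every per-layer
#' frequency starts at `omega0`. Fully reproducible from `seed`.
#'
#' @param in_dim coordinate dimensionality (image rank).
#' @param out_dim values predicted per coordinate (default 1).
#' @param width hidden units per layer.
#' @param depth number of weight layers (default 7: six sine layers plus a
#'   linear head). `depth = 2` is a pure affine model.
#' @param omega0 initial frequency (default 30).
#' @param seed integer seed.
#' @return an object of class `nif_model`.
#' @export
init_model <- function(in_dim, out_dim = 1L, width = 32L, depth = 7L,
                       omega0 = 30, seed = 0L) {
  if (!is_count(in_dim) || !is_count(out_dim) || !is_count(width))
    nif_stop("dims must be positive integers", "nif_error_arch")
  if (depth < 2) nif_stop("depth must be >= 2", "nif_error_arch")
  ld <- layer_dims(in_dim, out_dim, width, depth)
  nl <- length(ld$ins)
  model <- with_seed(seed, {
    W <- vector("list", nl)
    b <- vector("list", nl)
    for (l in seq_len(nl)) {
      fan_in <- ld$ins[l]
      bound <- if (l == 1L) 1 / fan_in else sqrt(6 / fan_in) / omega0
      W[[l]] <- matrix(runif(fan_in * ld$outs[l], -bound, bound),
                       fan_in, ld$outs[l])
      b[[l]] <- numeric(ld$outs[l])
    }
    list(W = W, b = b)
  })
  structure(list(
    depth = as.integer(depth), in_dim = as.integer(in_dim),
    out_dim = as.integer(out_dim), width = as.integer(width),
    W = model$W, b = model$b,
    omega = rep(omega0, max(0L, nl - 1L)),
    omega0 = omega0, seed = as.integer(seed)
  ), class = "nif_model")
}

#' Number of trainable scalars in a model
#'
#' Counts every weight, bias and per-layer frequency.
#'
#' @param model a `nif_model`, or missing when `in_dim`/`width`/... given.
#' @param in_dim,out_dim,width,depth architecture, as an alternative to
#'   passing a model.
#' @return integer count.
#' @export
parameter_count <- function(model = NULL, in_dim = NULL, out_dim = 1L,
                            width = NULL, depth = 7L) {
  if (!is.null(model)) {
    in_dim <- model$in_dim; out_dim <- model$out_dim
    width <- model$width; depth <- model$depth
  }
  ld <- layer_dims(in_dim, out_dim, width, depth)
  n_sine <- length(ld$ins) - 1L
  sum(ld$ins * ld$outs) + sum(ld$outs) + n_sine
}

#' @export
print.nif_model <- function(x, ...) {
  cat(sprintf("<nif_model> depth=%d width=%d in=%d out=%d params=%d omega0=%g\n",
              x$depth, x$width, x$in_dim, x$out_dim,
              parameter_count(x), x$omega0))
  invisible(x)
}

# Forward pass. `fast = TRUE` uses BLAS gemm (training); the default uses the
# row-independent deterministic product so any subset of coordinate rows
# yields bit-identical values to the full evaluation (the decoder contract).
# With `cache = TRUE` returns the activations needed by model_backward.
model_forward <- function(model, coords, fast = FALSE, cache = FALSE) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = model$in_dim)
  if (ncol(coords) != model$in_dim)
    nif_stop("coordinate dimensionality does not match in_dim", "nif_error_shape")
  if (length(coords) && !all(is.finite(coords)))
    nif_stop("non-finite coordinates", "nif_error_nonfinite")
  mm <- if (fast) function(a, b) a %*% b else mm_det
  nl <- length(model$W)
  h <- coords
  zs <- if (cache) vector("list", nl) else NULL
  hs <- if (cache) vector("list", nl) else NULL
  for (l in seq_len(nl)) {
    z <- mm(h, model$W[[l]])
    z <- sweep_add(z, model$b[[l]])
    if (l < nl) {
      if (cache) zs[[l]] <- z
      h <- sin(model$omega[l] * z)
      if (cache) hs[[l]] <- h
    } else {
      h <- z
    }
  }
  if (cache) list(out = h, zs = zs, hs = hs, coords = coords) else h
}

sweep_add <- function(m, v) {
  # adds a per-column bias; deterministic elementwise
  m + rep(v, each = nrow(m))
}

#' Evaluate the network at coordinates
#'
#' Deterministic and batch-invariant: evaluating any subset or split of the
#' rows gives exactly the values of the corresponding rows of a single call.
#'
#' @param model a `nif_model`.
#' @param coords numeric matrix, one coordinate per row, `in_dim` columns.
#' @return matrix of predicted values, `nrow(coords)` x `out_dim`.
#' @export
forward <- function(model, coords) {
  model_forward(model, coords, fast = FALSE, cache = FALSE)
}

# Backward pass: given d(loss)/d(pred) for the cached batch, returns
# gradients for every weight, bias and frequency.
model_backward <- function(model, cache, dout) {
  nl <- length(model$W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  gomega <- numeric(length(model$omega))
  h_prev <- if (nl == 1L) cache$coords else cache$hs[[nl - 1L]]
  dh <- dout
  gW[[nl]] <- crossprod(h_prev, dh)
  gb[[nl]] <- colSums(dh)
  if (nl > 1L) dh <- dh %*% t(model$W[[nl]])
  if (nl > 1L) {
    for (l in seq(nl - 1L, 1L)) {
      z <- cache$zs[[l]]
      cosz <- cos(model$omega[l] * z)
      dz <- dh * (model$omega[l] * cosz)
      gomega[l] <- sum(dh * z * cosz)
      h_in <- if (l == 1L) cache$coords else cache$hs[[l - 1L]]
      gW[[l]] <- crossprod(h_in, dz)
      gb[[l]] <- colSums(dz)
      if (l > 1L) dh <- dz %*% t(model$W[[l]])
    }
  }
  list(W = gW, b = gb, omega = gomega)
}

# Flatten parameters into the serialization order: for each layer its weight
# matrix (fan_in-major, i.e. column-by-output), then its bias; finally the
# per-layer frequencies.
pack_params <- function(model) {
  c(unlist(lapply(seq_along(model$W), function(l)
    c(as.vector(model$W[[l]]), model$b[[l]]))), model$omega)
}

unpack_params <- function(model, theta) {
  pos <- 0L
  for (l in seq_along(model$W)) {
    nw <- length(model$W[[l]])
    model$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(model$b[[l]])
    model$b[[l]][] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  if (length(model$omega)) {
    model$omega <- theta[pos + seq_along(model$omega)]
    pos <- pos + length(model$omega)
  }
  stopifnot(pos == length(theta))
  model
}

pack_grads <- function(model, grads) {
  c(unlist(lapply(seq_along(grads$W), function(l)
    c(as.vector(grads$W[[l]]), grads$b[[l]]))), grads$omega)
}
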