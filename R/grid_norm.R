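# Intensity normalization and coordinate grids.
#
# Training always happens on affinely rescaled intensities (default range
# 0..100) and on per-axis coordinates normalized to [-1, 1], the native input
# range of sinusoidal coordinate networks.

#' Min-max normalize an image to a target intensity range
#'
#' Maps pixel values affinely so the observed minimum lands on `lo` and the
#' observed maximum on `hi` (defaults 0 and 100). A constant image maps
#' entirely to `lo` with unit scale, so no division by zero occurs and the
#' map stays invertible on its range.
#'
#' @param img a [nif_image] (or bare array, treated as u16-less raw values).
#' @param lo,hi destination range, `hi > lo`.
#' @param probs optional length-2 quantile probabilities; when given, the
#'   source bounds are the corresponding quantiles instead of min/max and
#'   input is clipped to them first.
#' @param per_channel if `TRUE` and a C axis is present, each channel gets
#'   its own source bounds. Default `FALSE`: one global map preserves
#'   inter-channel brightness relations.
#' @return list with `image` (normalized [nif_image], dtype `f32`) and
#'   `params` (normalization parameters: `src_min`, `src_max`, `dst_lo`,
#'   `dst_hi`).
#' @export
minmax_normalize <- function(img, lo = 0, hi = 100, probs = NULL,
                             per_channel = FALSE) {
  x <- as_image_array(img)
  if (length(x) == 0) nif_stop("empty image", "nif_error_empty")
  if (!all(is.finite(x))) nif_stop("non-finite pixel values", "nif_error_nonfinite")
  if (!(hi > lo)) nif_stop("hi must exceed lo", "nif_error_range")
  axes <- if (inherits(img, "nif_image")) img$axes else NULL

  norm_one <- function(v) {
    if (!is.null(probs)) {
      b <- stats::quantile(v, probs, names = FALSE)
      v <- pmin(pmax(v, b[1]), b[2])
    } else b <- range(v)
    rng <- b[2] - b[1]
    scale <- if (rng > 0) (hi - lo) / rng else 1
    list(v = lo + (v - b[1]) * scale, src_min = b[1], src_max = b[2])
  }

  if (per_channel && !is.null(axes) && "C" %in% axes) {
    cax <- which(axes == "C")
    d <- length(dim(x))
    out <- x
    nmin <- numeric(dim(x)[cax]); nmax <- numeric(dim(x)[cax])
    for (ci in seq_len(dim(x)[cax])) {
      idx <- rep(list(quote(expr = )), d)
      idx[[cax]] <- ci
      ch <- do.call(`[`, c(list(x), idx, drop = FALSE))
      r <- norm_one(ch)
      out <- do.call(`[<-`, c(list(out), idx, list(array(r$v, dim(ch)))))
      nmin[ci] <- r$src_min; nmax[ci] <- r$src_max
    }
    params <- normalization_params(nmin, nmax, lo, hi)
    res <- out
  } else {
    r <- norm_one(as.vector(x))
    params <- normalization_params(r$src_min, r$src_max, lo, hi)
    res <- array(r$v, dim(x))
  }
  img_out <- if (inherits(img, "nif_image")) nif_image(res, img$axes, "f32")
             else nif_image(res, default_axes(dim(res)), "f32")
  list(image = img_out, params = params)
}

normalization_params <- function(src_min, src_max, dst_lo = 0, dst_hi = 100) {
  if (any(src_max < src_min)) nif_stop("src_max must be >= src_min", "nif_error_range")
  if (!(dst_hi > dst_lo)) nif_stop("dst_hi must exceed dst_lo", "nif_error_range")
  structure(list(src_min = src_min, src_max = src_max,
                 dst_lo = dst_lo, dst_hi = dst_hi),
            class = "nif_norm_params")
}

default_axes <- function(shape) {
  n <- length(shape)
  if (n > 5) nif_stop("at most 5 axes supported", "nif_error_axes")
  tail(CANONICAL_AXES, n)
}

#' Invert a min-max normalization
#'
#' Applies the inverse affine map, clips to the destination dtype's
#' representable range and rounds half-to-even for integer dtypes.
#'
#' @param img_norm normalized [nif_image] or array.
#' @param params parameters from [minmax_normalize()].
#' @param dtype_code target storage type (`"u8"`, `"u16"`, `"f32"`).
#' @return a [nif_image] in source units.
#' @export
denormalize <- function(img_norm, params, dtype_code) {
  info <- dtype_info(dtype_code)
  x <- as_image_array(img_norm)
  rng <- params$src_max - params$src_min
  scale <- ifelse(rng > 0, rng, 1) / (params$dst_hi - params$dst_lo)
  if (length(params$src_min) > 1L)
    nif_stop("per-channel denormalization requires denormalize_channels()", "nif_error_range")
  v <- params$src_min + (x - params$dst_lo) * scale
  v <- pmin(pmax(v, info$min), info$max)
  if (info$integer) {
    v <- round(v)  # round() is half-to-even in R
    storage.mode(v) <- "integer"
  }
  axes <- if (inherits(img_norm, "nif_image")) img_norm$axes else default_axes(dim(x))
  nif_image(array(v, dim(x)), axes, dtype_code)
}

axis_coord_values <- function(n) {
  if (n == 1L) return(0)                 # midpoint convention for extent 1
  -1 + 2 * (seq_len(n) - 1) / (n - 1)
}

#' Build the normalized coordinate grid for an image shape
#'
#' One row per pixel, in row-major order over the canonical axis order (last
#' axis fastest). Along an axis of extent n >= 2, index i maps to
#' -1 + 2i/(n-1); an axis of extent 1 maps to coordinate 0.
#'
#' @param shape integer extents (canonical axis order).
#' @return object of class `nif_grid` with `coords` (`prod(shape)` x
#'   `length(shape)` matrix) and `shape`.
#' @export
make_grid <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 0 || any(shape < 1))
    nif_stop("all extents must be >= 1", "nif_error_shape")
  n <- prod(shape)
  d <- length(shape)
  coords <- matrix(0, n, d)
  rep_each <- 1
  for (ax in rev(seq_len(d))) {
    vals <- axis_coord_values(shape[ax])
    coords[, ax] <- rep(rep(vals, each = rep_each), length.out = n)
    rep_each <- rep_each * shape[ax]
  }
  structure(list(coords = coords, shape = shape), class = "nif_grid")
}

#' Coordinates for an explicit set of pixel indices
#'
#' Applies the same per-axis map as [make_grid()] at the requested 0-based
#' multi-indices only; rows agree exactly with the corresponding rows of the
#' full grid.
#'
#' @param shape integer extents.
#' @param multi_indices numeric matrix, one 0-based multi-index per row.
#' @return coordinate matrix with one row per requested index.
#' @export
coords_for_indices <- function(shape, multi_indices) {
  shape <- as.integer(shape)
  if (is.null(dim(multi_indices)))
    multi_indices <- matrix(multi_indices, nrow = 1)
  if (ncol(multi_indices) != length(shape))
    nif_stop("index rank does not match shape", "nif_error_shape")
  if (any(multi_indices < 0) ||
      any(sweep(multi_indices, 2, shape, `>=`)))
    nif_stop("index out of bounds", "nif_error_bounds")
  out <- matrix(0, nrow(multi_indices), length(shape))
  for (ax in seq_along(shape)) {
    n <- shape[ax]
    out[, ax] <- if (n == 1L) 0 else -1 + 2 * multi_indices[, ax] / (n - 1)
  }
  out
}
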