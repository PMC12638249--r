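# Pixel-addressable decoding: the stored network is a pure function of
# coordinates, so any region of interest is decoded by evaluating exactly
# the requested pixels. All ROI modes share one evaluation path (the
# deterministic forward), so any ROI decode equals the corresponding
# selection from a full decode bit for bit.

#' ROI specifications for decoding
#'
#' @description
#' `roi_full()` decodes the whole image. `roi_slice(axis, index)` fixes one
#' axis at a 0-based index (the output keeps that axis with extent 1).
#' `roi_stride(strides)` decodes every s-th pixel per axis anchored at index
#' 0, giving extents `ceiling(n/s)`. `roi_indices(idx)` decodes an explicit
#' set of 0-based multi-indices (rows). `roi_mask(mask)` decodes where a
#' logical array is `TRUE`.
#'
#' @param axis axis label (e.g. `"Z"`) or 1-based axis position.
#' @param index 0-based index along `axis`.
#' @param strides positive integer stride per axis (scalar recycled, or
#'   named by axis label).
#' @param idx numeric matrix of 0-based multi-indices, one row per pixel.
#' @param mask logical array matching the stored shape.
#' @return an object of class `nif_roi`.
#' @export
roi_full <- function() structure(list(mode = "full"), class = "nif_roi")

#' @rdname roi_full
#' @export
roi_slice <- function(axis, index) {
  structure(list(mode = "slice", axis = axis, index = as.integer(index)),
            class = "nif_roi")
}

#' @rdname roi_full
#' @export
roi_stride <- function(strides) {
  if (any(strides < 1) || any(strides != floor(strides)))
    nif_stop("strides must be positive integers", "nif_error_range")
  structure(list(mode = "stride", strides = strides), class = "nif_roi")
}

#' @rdname roi_full
#' @export
roi_indices <- function(idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  structure(list(mode = "indices", idx = idx), class = "nif_roi")
}

#' @rdname roi_full
#' @export
roi_mask <- function(mask) {
  structure(list(mode = "mask", mask = mask), class = "nif_roi")
}

resolve_inif <- function(file) {
  if (inherits(file, "inif_file"))
    return(list(model = file$model, meta = file$meta))
  if (is.character(file)) {
    f <- read_inif(file)
    return(list(model = f$model, meta = f$meta))
  }
  if (is.list(file) && !is.null(file$model)) return(file)
  nif_stop("expected an inif_file object or a path", "nif_error_io")
}

axis_position <- function(axes, axis) {
  if (is.character(axis)) {
    p <- match(toupper(axis), axes)
    if (is.na(p)) nif_stop(sprintf("axis '%s' not stored", axis), "nif_error_axes")
    p
  } else {
    if (axis < 1 || axis > length(axes))
      nif_stop("axis position out of range", "nif_error_axes")
    as.integer(axis)
  }
}

# Evaluate the model at a set of 0-based multi-indices, in chunks; returns
# denormalized values in source-dtype units.
decode_at_indices <- function(model, meta, idx, chunk = 65536L) {
  shape <- as.integer(meta$shape)
  n <- nrow(idx)
  out <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    sel <- pos:min(n, pos + chunk - 1L)
    coords <- coords_for_indices(shape, idx[sel, , drop = FALSE])
    v <- model_forward(model, coords, fast = FALSE)[, 1L]
    out[sel] <- v
    pos <- pos + chunk
  }
  denorm_values(out, meta)
}

denorm_values <- function(v, meta) {
  nmp <- meta$norm
  info <- dtype_info(meta$dtype)
  v <- pmin(pmax(v, nmp$dst_lo), nmp$dst_hi)
  rng <- nmp$src_max - nmp$src_min
  scale <- (if (rng > 0) rng else 1) / (nmp$dst_hi - nmp$dst_lo)
  v <- nmp$src_min + (v - nmp$dst_lo) * scale
  v <- pmin(pmax(v, info$min), info$max)
  if (info$integer) v <- round(v)
  v
}

subgrid_indices <- function(axis_values) {
  lens <- vapply(axis_values, length, integer(1))
  n <- prod(lens)
  d <- length(axis_values)
  idx <- matrix(0, n, d)
  rep_each <- 1
  for (ax in rev(seq_len(d))) {
    idx[, ax] <- rep(rep(axis_values[[ax]], each = rep_each), length.out = n)
    rep_each <- rep_each * lens[ax]
  }
  idx
}

#' Decode an .inif file (fully or by region of interest)
#'
#' Evaluates the stored network only at the requested coordinates, then
#' inverts the stored normalization and casts to the source dtype (clip to
#' the training range, inverse affine map, clip to the dtype range, round
#' half to even).
#'
#' @param file an `inif_file` object or path.
#' @param roi a [roi_full()], [roi_slice()], [roi_stride()], [roi_indices()]
#'   or [roi_mask()] request.
#' @param chunk internal evaluation batch size; has no effect on the values.
#' @return a [nif_image] for `full`/`slice`/`stride` requests; for
#'   `indices`/`mask` a list with `values` (source-dtype units) and `idx`
#'   (the 0-based multi-indices, row-major order).
#' @export
decode <- function(file, roi = roi_full(), chunk = 65536L) {
  f <- resolve_inif(file)
  if (!is.null(f$meta$hybrid))
    nif_stop("hybrid file: use hybrid_decompress()", "nif_error_hybrid")
  meta <- f$meta
  shape <- as.integer(meta$shape)
  axes <- strsplit(meta$axes, "")[[1]]
  d <- length(shape)
  full_vals <- lapply(shape, function(n) 0:(n - 1L))

  if (roi$mode %in% c("indices", "mask")) {
    if (roi$mode == "mask") {
      mask <- roi$mask
      if (!identical(as.integer(dim(mask)), shape))
        nif_stop("mask shape mismatch", "nif_error_shape")
      p0 <- which(flatten_rm(mask)) - 1
      if (length(p0) == 0)
        return(list(values = numeric(0), idx = matrix(0, 0, d)))
      idx <- flat_to_multi(p0, shape)
    } else {
      idx <- roi$idx
      if (ncol(idx) != d) nif_stop("index rank mismatch", "nif_error_shape")
      if (any(idx < 0) || any(sweep(idx, 2, shape, `>=`)))
        nif_stop("index out of bounds", "nif_error_bounds")
    }
    vals <- decode_at_indices(f$model, meta, idx, chunk)
    return(list(values = vals, idx = idx))
  }

  axis_values <- switch(roi$mode,
    full = full_vals,
    slice = {
      p <- axis_position(axes, roi$axis)
      if (roi$index < 0 || roi$index >= shape[p])
        nif_stop("slice index out of range", "nif_error_bounds")
      av <- full_vals
      av[[p]] <- roi$index
      av
    },
    stride = {
      s <- roi$strides
      if (!is.null(names(s))) {
        sv <- rep(1L, d)
        pos <- vapply(names(s), function(a) axis_position(axes, a), integer(1))
        sv[pos] <- as.integer(s)
        s <- sv
      } else if (length(s) == 1L) {
        s <- rep(as.integer(s), d)
      }
      if (length(s) != d) nif_stop("one stride per axis required", "nif_error_shape")
      lapply(seq_len(d), function(ax) seq.int(0L, shape[ax] - 1L, by = s[ax]))
    },
    nif_stop("unknown ROI mode", "nif_error_roi")
  )
  idx <- subgrid_indices(axis_values)
  vals <- decode_at_indices(f$model, meta, idx, chunk)
  out_shape <- vapply(axis_values, length, integer(1))
  nif_image(unflatten_rm(vals, out_shape), axes, meta$dtype)
}

#' Decode only where a mask is true
#'
#' Equivalent to `decode(file, roi_mask(mask))`: returns the masked pixels'
#' values and their 0-based multi-indices, matching the masked selection of
#' a full decode exactly.
#'
#' @param file an `inif_file` object or path.
#' @param mask logical array matching the stored shape.
#' @return list with `values` and `idx`.
#' @export
decode_mask <- function(file, mask) {
  decode(file, roi_mask(mask))
}
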