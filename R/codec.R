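# Hybrid compression: a classic codec takes most of the byte budget, the
# coordinate network fits the residual, and a per-slice decision keeps
# whichever reconstruction scores better.

.codecs <- new.env(parent = emptyenv())

#' Define a codec adapter
#'
#' @param codec_id string identifier.
#' @param encode `function(img, byte_budget)` returning a raw payload (at
#'   most `byte_budget` bytes, best effort).
#' @param decode `function(payload)` returning a [nif_image] with the
#'   source's shape and dtype.
#' @param register also register the adapter for decoding by id.
#' @return a `nif_codec` list.
#' @export
codec_adapter <- function(codec_id, encode, decode, register = TRUE) {
  ad <- structure(list(codec_id = codec_id, encode = encode, decode = decode),
                  class = "nif_codec")
  if (register) assign(codec_id, ad, envir = .codecs)
  ad
}

get_codec <- function(codec_id) {
  if (!exists(codec_id, envir = .codecs, inherits = FALSE))
    nif_stop(sprintf("no codec adapter registered for '%s'", codec_id),
             "nif_error_codec")
  get(codec_id, envir = .codecs)
}

## ---- built-in toy codec ------------------------------------------------

# Payload layout (little endian): u8 ndim, u32 shape..., u8 dtype code index,
# u8 factor, f32 vmin, f32 vmax, then one quantized byte per retained sample.
DTYPE_CODES <- c("u8", "u16", "f32")

toy_encode <- function(img, byte_budget) {
  stopifnot(inherits(img, "nif_image"))
  shape <- img$shape
  d <- length(shape)
  sp <- spatial_axes(img$axes)
  header_bytes <- 1L + 4L * d + 1L + 1L + 8L
  n_for_factor <- function(f) {
    ext <- shape
    ext[sp] <- ceiling(shape[sp] / f)
    prod(ext)
  }
  f <- NA
  for (cand in seq_len(max(shape[sp]))) {
    if (header_bytes + n_for_factor(cand) <= byte_budget) { f <- cand; break }
  }
  if (is.na(f))
    nif_stop("byte budget too small for even one quantized sample",
             "nif_error_budget")
  ds <- block_mean_downsample(img$data, sp, f)
  vmin <- min(ds); vmax <- max(ds)
  q <- if (vmax > vmin) round((ds - vmin) / (vmax - vmin) * 255) else array(0, dim(ds))
  payload <- c(
    writeBin(as.integer(d), raw(), size = 1L),
    writeBin(as.integer(shape), raw(), size = 4L, endian = "little"),
    writeBin(match(img$dtype_code, DTYPE_CODES), raw(), size = 1L),
    writeBin(as.integer(f), raw(), size = 1L),
    writeBin(c(as.numeric(vmin), as.numeric(vmax)), raw(), size = 4L,
             endian = "little"),
    as.raw(flatten_rm(q))
  )
  payload
}

toy_decode <- function(payload) {
  d <- as.integer(payload[1])
  pos <- 1L
  shape <- readBin(payload[pos + 1:(4 * d)], "integer", n = d, size = 4L,
                   endian = "little")
  pos <- pos + 4L * d
  dtype_code <- DTYPE_CODES[as.integer(payload[pos + 1L])]
  f <- as.integer(payload[pos + 2L])
  vr <- readBin(payload[pos + 2L + 1:8], "double", n = 2L, size = 4L,
                endian = "little")
  pos <- pos + 2L + 8L
  axes <- default_axes(shape)
  sp <- which(axes %in% c("Z", "Y", "X"))
  ext <- shape
  ext[sp] <- ceiling(shape[sp] / f)
  q <- unflatten_rm(as.integer(payload[(pos + 1L):length(payload)]), ext)
  ds <- vr[1] + q / 255 * (vr[2] - vr[1])
  up <- linear_upsample(ds, shape, sp, f)
  info <- dtype_info(dtype_code)
  up <- pmin(pmax(up, info$min), info$max)
  if (info$integer) { up <- round(up); storage.mode(up) <- "integer" }
  nif_image(array(up, shape), axes, dtype_code)
}

block_mean_downsample <- function(arr, sp, f) {
  if (f == 1L) return(arr)
  for (ax in sp) {
    d <- dim(arr)
    n <- d[ax]
    groups <- (seq_len(n) - 1L) %/% f
    perm <- c(ax, seq_along(d)[-ax])
    m <- matrix(aperm(arr, perm), n)
    agg <- rowsum(m, groups) / as.vector(table(groups))
    nd <- d; nd[ax] <- nrow(agg)
    arr <- aperm(array(agg, nd[perm]), order(perm))
  }
  arr
}

linear_upsample <- function(arr, target_shape, sp, f) {
  if (f == 1L) return(arr)
  for (ax in sp) {
    d <- dim(arr)
    n_t <- target_shape[ax]
    n_s <- d[ax]
    centers <- (seq_len(n_s) - 1) * f + (f - 1) / 2
    centers <- pmin(centers, n_t - 1)
    perm <- c(ax, seq_along(d)[-ax])
    m <- matrix(aperm(arr, perm), n_s)
    xt <- 0:(n_t - 1)
    up <- apply(m, 2, function(col) {
      if (n_s == 1L) rep(col, n_t)
      else approx(centers, col, xout = xt, rule = 2)$y
    })
    up <- matrix(up, n_t)
    nd <- d; nd[ax] <- n_t
    arr <- aperm(array(up, nd[perm]), order(perm))
  }
  arr
}

#' Built-in deterministic toy codec
#'
#' Integer-factor downsampling of the spatial axes plus uniform 8-bit
#' quantization, with the factor chosen as the smallest one whose payload
#' fits the byte budget; decoding dequantizes and upsamples linearly.
#' Deterministic, dependency-free, and monotone: smaller budgets force
#' coarser factors.
#'
#' @return a `nif_codec` adapter with id `"toy"`.
#' @export
toy_codec <- function() codec_adapter("toy", toy_encode, toy_decode)

#' Lossless raw-store adapter
#'
#' Stores the pixels verbatim (ignoring the budget, which it reports by
#' overshooting). Useful for testing the hybrid path with a zero residual.
#' @return a `nif_codec` adapter with id `"rawstore"`.
#' @export
raw_codec <- function() {
  codec_adapter(
    "rawstore",
    encode = function(img, byte_budget) {
      d <- length(img$shape)
      c(writeBin(as.integer(d), raw(), size = 1L),
        writeBin(as.integer(img$shape), raw(), size = 4L, endian = "little"),
        writeBin(match(img$dtype_code, DTYPE_CODES), raw(), size = 1L),
        writeBin(as.numeric(flatten_rm(img$data)), raw(), size = 8L,
                 endian = "little"))
    },
    decode = function(payload) {
      d <- as.integer(payload[1])
      shape <- readBin(payload[1 + 1:(4 * d)], "integer", n = d, size = 4L,
                       endian = "little")
      dtype_code <- DTYPE_CODES[as.integer(payload[4 * d + 2L])]
      v <- readBin(payload[(4 * d + 3L):length(payload)], "double",
                   n = prod(shape), size = 8L, endian = "little")
      x <- unflatten_rm(v, shape)
      if (dtype_info(dtype_code)$integer) storage.mode(x) <- "integer"
      nif_image(x, default_axes(shape), dtype_code)
    })
}

## ---- slice decisions ---------------------------------------------------

slice_axis_position <- function(axes) {
  if ("Z" %in% axes) which(axes == "Z")
  else if ("T" %in% axes) which(axes == "T")
  else NA_integer_
}

extract_slice <- function(arr, axis, i) {
  d <- length(dim(arr))
  idx <- rep(list(quote(expr = )), d)
  idx[[axis]] <- i
  do.call(`[`, c(list(arr), idx, drop = FALSE))
}

#' Per-slice choice between codec-only and adapted reconstructions
#'
#' Slices along Z when present, else T, else the whole image is a single
#' slice. A slice is overwritten by the adapted (codec + residual)
#' reconstruction only when it strictly improves the metric; ties keep the
#' codec-only slice.
#'
#' @param img original [nif_image].
#' @param codec_recon,adapted_recon reconstructions with the same shape.
#' @param metric_id `"psnr"`, `"ssim"` or a `function(recon, raw)` returning
#'   a larger-is-better score.
#' @return logical vector, one decision per slice (`TRUE` = use adapted).
#' @export
decide_slices <- function(img, codec_recon, adapted_recon, metric_id = "psnr") {
  a <- as_image_array(img)
  cr <- as_image_array(codec_recon)
  ar <- as_image_array(adapted_recon)
  if (!identical(dim(a), dim(cr)) || !identical(dim(a), dim(ar)))
    nif_stop("shape mismatch", "nif_error_shape")
  rng <- metric_data_range(img)
  metric <- if (is.function(metric_id)) metric_id
  else switch(metric_id,
    psnr = function(x, y) psnr(x, y, data_range = rng),
    ssim = function(x, y) ssim(x, y, data_range = rng),
    nif_stop(sprintf("unknown metric '%s'", metric_id), "nif_error_metric"))
  ax <- slice_axis_position(if (inherits(img, "nif_image")) img$axes
                            else default_axes(dim(a)))
  if (is.na(ax)) {
    return(metric(ar, a) > metric(cr, a))
  }
  n <- dim(a)[ax]
  vapply(seq_len(n), function(i) {
    metric(extract_slice(ar, ax, i), extract_slice(a, ax, i)) >
      metric(extract_slice(cr, ax, i), extract_slice(a, ax, i))
  }, logical(1))
}

## ---- hybrid pipeline ---------------------------------------------------

#' Hybrid compression with a codec prior
#'
#' Allocates `split` (default 90%) of the byte budget
#' `floor(raw_bytes / target_cr)` to the codec, computes the residual
#' between the normalized image and the normalized codec reconstruction,
#' rescales it into the training range, and fits the coordinate network to
#' the residual under the remaining budget. Per-slice decisions then record
#' where the adapted reconstruction actually improves on the codec alone.
#'
#' @param img a [nif_image].
#' @param codec a `nif_codec` adapter (e.g. [toy_codec()]).
#' @param target_cr target compression ratio for the whole hybrid file.
#' @param split codec share of the bitstream, in (0, 1); default 0.9.
#' @param cfg a [compression_config()] controlling the residual fit (its
#'   `target_cr` is ignored).
#' @param metric_id slice-decision metric (see [decide_slices()]).
#' @param path output path.
#' @return an `inif_file` object whose header carries the hybrid block.
#' @export
hybrid_compress <- function(img, codec, target_cr, split = 0.9, cfg,
                            metric_id = "psnr",
                            path = tempfile(fileext = ".inif")) {
  stopifnot(inherits(img, "nif_image"), inherits(codec, "nif_codec"))
  if (split <= 0 || split >= 1)
    nif_stop("split must be in (0, 1)", "nif_error_range")
  raw_bytes <- raw_pixel_bytes(img$shape, img$dtype_code)
  total_budget <- floor(raw_bytes / target_cr)
  codec_budget <- floor(split * raw_bytes / target_cr)
  payload <- codec$encode(img, codec_budget)
  codec_recon <- codec$decode(payload)

  nm <- minmax_normalize(img)
  codec_norm <- normalize_with(codec_recon$data, nm$params)
  resid <- nm$image$data - codec_norm
  rmin <- min(resid); rmax <- max(resid)
  resid01 <- if (rmax > rmin) (resid - rmin) / (rmax - rmin) * 100
             else array(0, dim(resid))

  hybrid_block <- list(
    codec_id = codec$codec_id, split = split,
    residual_map = list(rmin = rmin, rmax = rmax),
    decisions = rep(TRUE, 2L)   # placeholder for header sizing
  )
  # A well-behaved codec leaves at least the (1 - split) share; an adapter
  # that overshot its budget (reported via achieved_cr) must not starve the
  # residual fit, which then gets its nominal share.
  residual_budget <- max(total_budget - length(payload),
                         floor((1 - split) * total_budget))
  width <- plan_for_budget(residual_budget, img$shape, img$dtype_code,
                           depth = cfg$depth,
                           bytes_per_param = cfg$bytes_per_param,
                           axes = img$axes,
                           extra = list(hybrid = within_decisions(
                             hybrid_block, n_slices(img))))
  fit <- train_engine(flatten_rm(array(resid01, dim(resid))), img$shape,
                      width, cfg)

  # adapted reconstruction, decoded exactly as hybrid_decompress will
  res_meta <- inif_metadata(
    axes = img$axes, shape = img$shape, dtype_code = img$dtype_code,
    norm = nm$params, depth = cfg$depth, width = width,
    in_dim = length(img$shape), out_dim = 1L,
    omega0 = cfg$optimizer_params$omega0 %||% 30,
    seed = cfg$seed, bytes_per_param = cfg$bytes_per_param)
  adapted <- hybrid_reconstruct(fit$model, res_meta, codec_recon$data,
                                nm$params, rmin, rmax,
                                decisions = NULL, img$axes)
  decisions <- decide_slices(img, codec_recon, adapted, metric_id)
  hybrid_block$decisions <- decisions
  bytes <- write_inif(fit$model,
                      modifyList(res_meta, list(hybrid = hybrid_block)),
                      path, codec_payload = payload)
  structure(list(
    path = path, meta = modifyList(res_meta, list(hybrid = hybrid_block)),
    model = fit$model, trace = fit$trace, file_bytes = bytes,
    raw_bytes = raw_bytes, codec_bytes = length(payload),
    codec_budget = codec_budget,
    achieved_cr = compression_ratio(raw_bytes, bytes),
    decisions = decisions
  ), class = c("inif_hybrid_file", "inif_file"))
}

n_slices <- function(img) {
  ax <- slice_axis_position(img$axes)
  if (is.na(ax)) 1L else img$shape[ax]
}

within_decisions <- function(block, n) {
  block$decisions <- rep(TRUE, n)
  block
}

normalize_with <- function(arr, params) {
  rng <- params$src_max - params$src_min
  scale <- (params$dst_hi - params$dst_lo) / (if (rng > 0) rng else 1)
  params$dst_lo + (arr - params$src_min) * scale
}

# Shared reconstruction: codec plane + (where decided) residual plane, all in
# the normalized domain, then denormalized to the source dtype.
hybrid_reconstruct <- function(model, meta, codec_data, params, rmin, rmax,
                               decisions, axes) {
  shape <- as.integer(meta$shape)
  resid_meta <- meta
  resid_meta$hybrid <- NULL
  grid_idx <- subgrid_indices(lapply(shape, function(n) 0:(n - 1L)))
  vals <- numeric(nrow(grid_idx))
  pos <- 1L
  while (pos <= nrow(grid_idx)) {
    sel <- pos:min(nrow(grid_idx), pos + 65535L)
    coords <- coords_for_indices(shape, grid_idx[sel, , drop = FALSE])
    vals[sel] <- model_forward(model, coords, fast = FALSE)[, 1L]
    pos <- pos + 65536L
  }
  vals <- pmin(pmax(vals, 0), 100)
  resid <- rmin + vals / 100 * (rmax - rmin)
  resid_arr <- unflatten_rm(resid, shape)
  codec_norm <- normalize_with(codec_data, params)
  combined <- codec_norm + resid_arr
  if (!is.null(decisions)) {
    ax <- slice_axis_position(axes)
    if (is.na(ax)) {
      if (!decisions[1]) combined <- codec_norm
    } else {
      d <- length(shape)
      for (i in which(!decisions)) {
        idx <- rep(list(quote(expr = )), d)
        idx[[ax]] <- i
        combined <- do.call(`[<-`, c(list(combined), idx,
                                     list(extract_slice(codec_norm, ax, i))))
      }
    }
  }
  info <- dtype_info(meta$dtype)
  v <- normalize_inverse(combined, params)
  v <- pmin(pmax(v, info$min), info$max)
  if (info$integer) { v <- round(v); storage.mode(v) <- "integer" }
  nif_image(array(v, shape), axes, meta$dtype)
}

normalize_inverse <- function(arr, params) {
  rng <- params$src_max - params$src_min
  scale <- (if (rng > 0) rng else 1) / (params$dst_hi - params$dst_lo)
  params$src_min + (arr - params$dst_lo) * scale
}

#' Decompress a hybrid file
#'
#' Per slice: the codec reconstruction plus the decoded residual where the
#' stored decision says the adapted result won, else the codec
#' reconstruction alone; denormalized to the source dtype.
#'
#' @param file an `inif_hybrid_file` object or path.
#' @param codec optional `nif_codec` adapter; defaults to the registered
#'   adapter named in the file header.
#' @return a [nif_image].
#' @export
hybrid_decompress <- function(file, codec = NULL) {
  f <- if (is.character(file)) read_inif(file)
       else list(model = file$model, meta = file$meta,
                 codec_payload = read_inif(file$path)$codec_payload)
  meta <- f$meta
  if (is.null(meta$hybrid))
    nif_stop("not a hybrid file", "nif_error_hybrid")
  if (is.null(codec)) codec <- get_codec(meta$hybrid$codec_id)
  codec_recon <- codec$decode(f$codec_payload)
  params <- normalization_params(meta$norm$src_min, meta$norm$src_max,
                                 meta$norm$dst_lo, meta$norm$dst_hi)
  axes <- strsplit(meta$axes, "")[[1]]
  hybrid_reconstruct(f$model, meta, codec_recon$data, params,
                     meta$hybrid$residual_map$rmin,
                     meta$hybrid$residual_map$rmax,
                     as.logical(meta$hybrid$decisions), axes)
}
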