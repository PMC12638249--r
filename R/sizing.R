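# Translating a target compression ratio into a model architecture whose
# serialized file respects the byte budget.
#
# The ratio is defined against the on-disk container size INCLUDING header
# metadata, so the "achieved >= target" guarantee is honest. raw_bytes is the
# uncompressed pixel payload (extents x dtype bytes), container-independent.

#' Compression ratio
#'
#' @param raw_bytes uncompressed pixel payload in bytes.
#' @param file_bytes on-disk compressed size in bytes.
#' @return `raw_bytes / file_bytes`.
#' @export
compression_ratio <- function(raw_bytes, file_bytes) {
  if (file_bytes <= 0) nif_stop("file_bytes must be > 0", "nif_error_range")
  raw_bytes / file_bytes
}

# Upper bound on the serialized header size for a given architecture: the
# header is rendered with worst-case-length stand-ins for every value not
# known until after training (normalization bounds, checksum).
estimate_header_bytes <- function(shape, axes, dtype_code, depth, width,
                                  in_dim, out_dim, bytes_per_param,
                                  omega0 = 30, seed = 0L, extra = NULL) {
  worst <- -1.7976931348623157e+308   # longest plain-double rendering
  np <- parameter_count(in_dim = in_dim, out_dim = out_dim,
                        width = width, depth = depth)
  meta <- inif_metadata(
    axes = axes, shape = shape, dtype_code = dtype_code,
    norm = normalization_params(worst, -worst, worst, -worst),
    depth = depth, width = width, in_dim = in_dim, out_dim = out_dim,
    omega0 = worst, seed = seed, bytes_per_param = bytes_per_param,
    extra = extra)
  meta$payload_len <- np * bytes_per_param
  meta$crc32 <- "ffffffff"
  length(render_header(meta))
}

#' Plan a model architecture for a target compression ratio
#'
#' Chooses the largest hidden width whose serialized container (magic +
#' header + weight payload) fits within `floor(raw_bytes / target_cr)` bytes,
#' so the achieved ratio is guaranteed to be at least the target.
#'
#' @param shape image extents (canonical axis order).
#' @param dtype_code source storage type (`"u8"`, `"u16"`, `"f32"`).
#' @param target_cr requested compression ratio, `> 1`.
#' @param depth weight-layer count (default 7).
#' @param bytes_per_param 4 (float32, default) or 2 (float16).
#' @param out_dim values per coordinate (default 1).
#' @param axes axis labels (defaults to trailing canonical axes).
#' @return object of class `nif_plan`: `raw_bytes`, `target_cr`,
#'   `chosen_width`, `depth`, `header_bytes`, `predicted_file_bytes`,
#'   `achieved_cr` (predicted; the trainer recomputes it from the real file).
#' @export
plan_architecture <- function(shape, dtype_code, target_cr, depth = 7L,
                              bytes_per_param = 4L, out_dim = 1L,
                              axes = NULL) {
  if (!(target_cr > 1)) nif_stop("target_cr must exceed 1", "nif_error_range")
  if (!bytes_per_param %in% c(2L, 4L))
    nif_stop("bytes_per_param must be 2 or 4", "nif_error_range")
  if (is.null(axes)) axes <- default_axes(shape)
  in_dim <- length(shape)
  raw_bytes <- raw_pixel_bytes(shape, dtype_code)
  budget <- floor(raw_bytes / target_cr)

  total_bytes <- function(w) {
    np <- parameter_count(in_dim = in_dim, out_dim = out_dim,
                          width = w, depth = depth)
    hb <- estimate_header_bytes(shape, axes, dtype_code, depth, w,
                                in_dim, out_dim, bytes_per_param)
    8 + hb + np * bytes_per_param    # magic(4) + header_len(4) + header + payload
  }

  if (total_bytes(1L) > budget) {
    min_cr <- raw_bytes / total_bytes(1L)
    nif_stop(sprintf(
      "target_cr %.6g infeasible: even width 1 needs %d bytes; minimal feasible CR is %.6g",
      target_cr, total_bytes(1L), min_cr), "nif_error_budget",
      minimal_feasible_cr = min_cr)
  }
  if (depth == 2L) {
    w <- 1L      # a pure affine model has no hidden width to size
  } else {
    lo <- 1L
    hi <- 2L
    while (total_bytes(hi) <= budget) { lo <- hi; hi <- hi * 2L }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (total_bytes(mid) <= budget) lo <- mid else hi <- mid
    }
    w <- lo
  }
  pred <- total_bytes(w)
  structure(list(
    raw_bytes = raw_bytes, target_cr = target_cr,
    header_bytes = pred - 8 -
      parameter_count(in_dim = in_dim, out_dim = out_dim,
                      width = w, depth = depth) * bytes_per_param,
    bytes_per_param = as.integer(bytes_per_param),
    chosen_width = as.integer(w), depth = as.integer(depth),
    in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
    predicted_file_bytes = pred,
    achieved_cr = raw_bytes / pred
  ), class = "nif_plan")
}

# Largest width whose container fits an absolute byte budget (used by the
# hybrid mode, where the residual model gets whatever the codec left over).
plan_for_budget <- function(budget_bytes, shape, dtype_code,
                            depth = 7L, bytes_per_param = 4L, out_dim = 1L,
                            axes = NULL, extra = NULL) {
  if (is.null(axes)) axes <- default_axes(shape)
  in_dim <- length(shape)
  total_bytes <- function(w) {
    np <- parameter_count(in_dim = in_dim, out_dim = out_dim,
                          width = w, depth = depth)
    hb <- estimate_header_bytes(shape, axes, dtype_code, depth, w,
                                in_dim, out_dim, bytes_per_param,
                                extra = extra)
    8 + hb + np * bytes_per_param
  }
  if (total_bytes(1L) > budget_bytes)
    nif_stop(sprintf("budget of %d bytes below the minimal model (%d bytes)",
                     budget_bytes, total_bytes(1L)), "nif_error_budget")
  if (depth == 2L) return(1L)
  lo <- 1L; hi <- 2L
  while (total_bytes(hi) <= budget_bytes) { lo <- hi; hi <- hi * 2L }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (total_bytes(mid) <= budget_bytes) lo <- mid else hi <- mid
  }
  lo
}

#' @export
print.nif_plan <- function(x, ...) {
  cat(sprintf(
    "<nif_plan> raw=%d B, target CR=%g, width=%d (depth %d), predicted file=%d B, predicted CR=%.2f\n",
    x$raw_bytes, x$target_cr, x$chosen_width, x$depth,
    x$predicted_file_bytes, x$achieved_cr))
  invisible(x)
}
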