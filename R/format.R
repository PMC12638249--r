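# The .inif container: 4-byte magic "NIF1", a little-endian uint32 header
# length, a UTF-8 JSON header, then the weight payload (little-endian
# float32 or float16 scalars: per layer the weight matrix in fan-in-major
# order then the bias, finally the per-layer frequencies). Hybrid files
# append the codec payload after the weights; its length and checksum live
# in the header's hybrid block. The weight payload carries a CRC-32.

INIF_MAGIC <- charToRaw("NIF1")
INIF_VERSION <- 1L

# Round doubles through IEEE float32 storage.
f32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

f16_round <- function(x) .f16_bits_to_double(.f32_to_f16_bits(as.numeric(x)))

crc32_hex <- function(bytes) {
  v <- .crc32_raw(bytes)            # unsigned 32-bit value carried in a double
  sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
}

#' Build the header metadata for an .inif file
#'
#' Assembles the ordered header block [write_inif()] serializes: axis
#' labels, shape, dtype, normalization parameters, architecture and seed.
#' [compress()] calls this internally; it is exported for writing files
#' from models constructed by hand.
#'
#' @param axes character vector of axis labels.
#' @param shape integer extents.
#' @param dtype_code source storage type.
#' @param norm normalization parameters (the `params` element returned by
#'   [minmax_normalize()]).
#' @param depth,width,in_dim,out_dim,omega0 model architecture.
#' @param seed the seed recorded for provenance.
#' @param bytes_per_param 4 (float32) or 2 (float16).
#' @param extra optional list with `guidance` and/or `hybrid` blocks.
#' @return a named list in header order.
#' @export
inif_metadata <- function(axes, shape, dtype_code, norm, depth, width,
                          in_dim, out_dim, omega0, seed, bytes_per_param,
                          extra = NULL) {
  meta <- list(
    format_version = INIF_VERSION,
    axes = paste(axes, collapse = ""),
    shape = as.integer(shape),
    dtype = dtype_code,
    norm = list(src_min = norm$src_min, src_max = norm$src_max,
                dst_lo = norm$dst_lo, dst_hi = norm$dst_hi),
    arch = list(depth = as.integer(depth), width = as.integer(width),
                in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                omega0 = omega0),
    bytes_per_param = as.integer(bytes_per_param),
    seed = as.integer(seed)
  )
  if (!is.null(extra$guidance)) meta$guidance <- extra$guidance
  if (!is.null(extra$hybrid)) meta$hybrid <- extra$hybrid
  meta
}

render_header <- function(meta) {
  meta$shape <- I(meta$shape)
  if (!is.null(meta$hybrid$decisions)) meta$hybrid$decisions <- I(meta$hybrid$decisions)
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null")
  charToRaw(as.character(json))
}

#' Write a model to an .inif container
#'
#' Weights are stored as little-endian float32 (or float16 when the metadata
#' says `bytes_per_param = 2`); the payload carries a CRC-32 recorded in the
#' JSON header. The header holds everything needed to decode without the
#' source image.
#'
#' @param model a `nif_model`.
#' @param metadata header list from the trainer (see [compress()]); must
#'   contain axes, shape, dtype, normalization and architecture blocks.
#' @param path output path.
#' @param codec_payload optional raw vector appended after the weights
#'   (hybrid mode).
#' @return number of bytes written.
#' @export
write_inif <- function(model, metadata, path, codec_payload = NULL) {
  theta <- pack_params(model)
  bpp <- metadata$bytes_per_param %||% 4L
  payload <- if (bpp == 4L) {
    writeBin(as.numeric(theta), raw(), size = 4L, endian = "little")
  } else {
    bits <- .f32_to_f16_bits(theta)
    bits[bits > 32767L] <- bits[bits > 32767L] - 65536L
    writeBin(as.integer(bits), raw(), size = 2L, endian = "little")
  }
  metadata$payload_len <- length(payload)
  metadata$crc32 <- crc32_hex(payload)
  if (!is.null(codec_payload)) {
    if (is.null(metadata$hybrid)) metadata$hybrid <- list()
    metadata$hybrid$codec_len <- length(codec_payload)
    metadata$hybrid$codec_crc32 <- crc32_hex(codec_payload)
  }
  header <- render_header(metadata)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(INIF_MAGIC, con)
  writeBin(length(header), con, size = 4L, endian = "little")
  writeBin(header, con)
  writeBin(payload, con)
  if (!is.null(codec_payload)) writeBin(codec_payload, con)
  8L + length(header) + length(payload) +
    if (is.null(codec_payload)) 0L else length(codec_payload)
}

#' Read an .inif container
#'
#' Validates magic, version, payload length and checksum (each failure has a
#' distinct condition class: `nif_error_magic`, `nif_error_version`,
#' `nif_error_truncated`, `nif_error_checksum`) and reconstructs a model
#' whose forward evaluations are bit-identical to the serialized one.
#'
#' @param path path to an `.inif` file.
#' @return list with `model` (a `nif_model`), `meta` (header list) and
#'   `codec_payload` (raw vector or `NULL`).
#' @export
read_inif <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) nif_stop(sprintf("cannot read '%s'", path), "nif_error_io")
  bytes <- readBin(path, raw(), n = sz)
  if (length(bytes) < 8L) nif_stop("truncated file", "nif_error_truncated")
  if (!identical(bytes[1:4], INIF_MAGIC))
    nif_stop("bad magic: not an INIF file", "nif_error_magic")
  hl <- readBin(bytes[5:8], "integer", size = 4L, endian = "little")
  if (hl < 2L || 8L + hl > length(bytes))
    nif_stop("truncated header", "nif_error_truncated")
  meta <- jsonlite::fromJSON(rawToChar(bytes[9:(8L + hl)]), simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), INIF_VERSION))
    nif_stop(sprintf("unsupported format_version %s", meta$format_version),
             "nif_error_version")
  off <- 8L + hl
  plen <- as.integer(meta$payload_len)
  if (off + plen > length(bytes))
    nif_stop("truncated payload", "nif_error_truncated")
  payload <- bytes[(off + 1L):(off + plen)]
  if (!identical(crc32_hex(payload), meta$crc32))
    nif_stop("payload checksum mismatch", "nif_error_checksum")
  bpp <- as.integer(meta$bytes_per_param)
  theta <- if (bpp == 4L) {
    readBin(payload, "double", n = plen / 4L, size = 4L, endian = "little")
  } else {
    .f16_bits_to_double(readBin(payload, "integer", n = plen / 2L,
                                size = 2L, signed = FALSE, endian = "little"))
  }
  arch <- meta$arch
  model <- init_model(arch$in_dim, arch$out_dim, max(1L, arch$width),
                      arch$depth, arch$omega0, seed = 0L)
  model <- unpack_params(model, theta)
  codec_payload <- NULL
  if (!is.null(meta$hybrid)) {
    clen <- as.integer(meta$hybrid$codec_len)
    if (off + plen + clen > length(bytes))
      nif_stop("truncated payload", "nif_error_truncated")
    codec_payload <- bytes[(off + plen + 1L):(off + plen + clen)]
    if (!identical(crc32_hex(codec_payload), meta$hybrid$codec_crc32))
      nif_stop("codec payload checksum mismatch", "nif_error_checksum")
  }
  list(model = model, meta = meta, codec_payload = codec_payload)
}

#' Print the header of an .inif file
#'
#' @param path path to an `.inif` file.
#' @return invisibly, the header list.
#' @export
inif_info <- function(path) {
  f <- read_inif(path)
  cat(jsonlite::toJSON(f$meta, auto_unbox = TRUE, pretty = TRUE, digits = NA))
  cat("\n")
  invisible(f$meta)
}
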