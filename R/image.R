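CANONICAL_AXES <- c("T", "C", "Z", "Y", "X")

DTYPE_INFO <- list(
  u8  = list(bytes = 1L, min = 0, max = 255, integer = TRUE),
  u16 = list(bytes = 2L, min = 0, max = 65535, integer = TRUE),
  f32 = list(bytes = 4L, min = -Inf, max = Inf, integer = FALSE)
)

dtype_info <- function(dtype_code) {
  info <- DTYPE_INFO[[dtype_code]]
  if (is.null(info)) nif_stop(sprintf("unknown dtype_code '%s'", dtype_code), "nif_error_dtype")
  info
}

#' Multidimensional image tensor
#'
#' Container for an N-dimensional microscopy image with labeled axes. Axes are
#' a subset of T (time), C (channel), Z (depth), Y, X, always stored in that
#' canonical order; readers reorder on load.
#'
#' @param data numeric array (a plain vector is treated as 1-D).
#' @param axes character vector of axis labels, one per array dimension,
#'   drawn from `c("T","C","Z","Y","X")` in canonical order.
#' @param dtype_code source storage type: `"u8"`, `"u16"` or `"f32"`.
#' @return an object of class `nif_image` with fields `data`, `axes`,
#'   `dtype_code`, `shape`.
#' @export
nif_image <- function(data, axes, dtype_code = "u16") {
  if (is.null(dim(data))) dim(data) <- length(data)
  shape <- dim(data)
  axes <- toupper(as.character(axes))
  if (length(axes) != length(shape))
    nif_stop("length(axes) must equal the array rank", "nif_error_axes")
  if (anyDuplicated(axes) || !all(axes %in% CANONICAL_AXES))
    nif_stop("axes must be unique labels from T,C,Z,Y,X", "nif_error_axes")
  ord <- match(axes, CANONICAL_AXES)
  if (is.unsorted(ord)) {
    perm <- order(ord)
    data <- aperm(data, perm)
    axes <- axes[perm]
    shape <- dim(data)
  }
  if (any(shape < 1)) nif_stop("all extents must be >= 1", "nif_error_shape")
  dtype_info(dtype_code)
  structure(
    list(data = data, axes = axes, dtype_code = dtype_code, shape = shape),
    class = "nif_image"
  )
}

#' @export
print.nif_image <- function(x, ...) {
  cat(sprintf(
    "<nif_image> %s [%s] dtype=%s range=[%g, %g]\n",
    paste(x$shape, collapse = "x"), paste(x$axes, collapse = ""),
    x$dtype_code, min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.nif_image <- function(x) x$shape

as_image_array <- function(img) {
  if (inherits(img, "nif_image")) img$data else img
}

raw_pixel_bytes <- function(shape, dtype_code) {
  prod(shape) * dtype_info(dtype_code)$bytes
}

# Spatial axes (Z/Y/X) positions within an image's axis vector.
spatial_axes <- function(axes) which(axes %in% c("Z", "Y", "X"))

#' Read a TIFF image into a labeled tensor
#'
#' Reads single- or multi-plane TIFF files. Each plane is a Y-by-X matrix;
#' leading axes (any of T, C, Z) are folded over the plane sequence in
#' row-major order. TIFF itself does not carry the axis labels, so files with
#' more than one leading axis need the `axes`/`shape` hints.
#'
#' @param path file path.
#' @param axes axis labels, e.g. `"ZYX"`; defaults to `"YX"` for single-plane
#'   files and `"ZYX"` for stacks.
#' @param shape full extents when more than one leading axis is present.
#' @param dtype_code override the storage type inferred from bit depth.
#' @return a [nif_image].
#' @export
read_image <- function(path, axes = NULL, shape = NULL, dtype_code = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  nb <- attr(planes[[1]], "bits.per.sample")
  is_float <- !is.null(nb) && nb == 32L
  if (!is_float) planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.null(dtype_code)) {
    dtype_code <- if (is_float) "f32" else if (nb <= 8) "u8" else "u16"
  }
  np <- length(planes)
  pd <- dim(planes[[1]])
  if (is.null(axes)) axes <- if (np == 1L) "YX" else "ZYX"
  axes <- strsplit(toupper(axes), "")[[1]]
  lead <- setdiff(axes, c("Y", "X"))
  if (is.null(shape)) {
    if (length(lead) > 1L)
      nif_stop("shape hint required for more than one leading axis", "nif_error_axes")
    shape <- c(if (length(lead)) np, pd)
  }
  if (prod(shape[seq_along(lead)]) != np || !all(shape[length(lead) + 1:2] == pd))
    nif_stop("shape hint inconsistent with the file's planes", "nif_error_shape")
  arr <- array(0, dim = shape)
  # planes are ordered row-major over the leading axes
  lead_shape <- shape[seq_along(lead)]
  flat <- unlist(lapply(planes, function(p) as.vector(t(p))))  # row-major YX
  arr <- unflatten_rm(flat, shape)
  nif_image(arr, axes, dtype_code)
}

#' Write a labeled tensor to a (multi-plane) TIFF file
#'
#' @param img a [nif_image].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "nif_image"))
  if (!all(c("Y", "X") %in% img$axes))
    nif_stop("TIFF output needs Y and X axes", "nif_error_axes")
  info <- dtype_info(img$dtype_code)
  d <- length(img$shape)
  ny <- img$shape[d - 1L]; nx <- img$shape[d]
  nplanes <- prod(img$shape) / (ny * nx)
  flat <- flatten_rm(img$data)
  if (info$integer) {
    bits <- if (img$dtype_code == "u8") 8 else 16
    sc <- 2^bits - 1
    planes <- lapply(seq_len(nplanes), function(i) {
      v <- flat[((i - 1) * ny * nx + 1):(i * ny * nx)]
      matrix(v / sc, ny, nx, byrow = TRUE)
    })
    tiff::writeTIFF(if (nplanes == 1L) planes[[1]] else planes, path,
                    bits.per.sample = bits)
  } else {
    planes <- lapply(seq_len(nplanes), function(i) {
      v <- flat[((i - 1) * ny * nx + 1):(i * ny * nx)]
      matrix(v, ny, nx, byrow = TRUE)
    })
    tiff::writeTIFF(if (nplanes == 1L) planes[[1]] else planes, path,
                    bits.per.sample = 32)
  }
  invisible(path)
}
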