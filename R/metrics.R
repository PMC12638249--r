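# Reconstruction quality metrics. Computed in source-dtype units with
# data_range = dtype max (u8: 255, u16: 65535) by convention; float images
# fall back to the observed range of the reference.

metric_data_range <- function(img) {
  if (!inherits(img, "nif_image")) return(diff(range(img)))
  info <- dtype_info(img$dtype_code)
  if (is.finite(info$max)) info$max - info$min else diff(range(img$data))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB; identical inputs return `Inf`.
#'
#' @param a,b arrays or [nif_image]s of equal shape.
#' @param data_range signal range; defaults to the dtype maximum of `a`.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = NULL) {
  if (is.null(data_range)) data_range <- metric_data_range(a)
  x <- as_image_array(a); y <- as_image_array(b)
  if (!identical(dim(x), dim(y)) && length(x) != length(y))
    nif_stop("shape mismatch", "nif_error_shape")
  if (data_range <= 0) nif_stop("data_range must be > 0", "nif_error_range")
  mse <- mean((as.numeric(x) - as.numeric(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_window_1d <- function(sigma = 1.5, radius = 5L) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Valid-mode separable 2D filtering via banded matrices: rows then columns.
valid_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  m <- n - 2L * r
  if (m < 1L) nif_stop("image smaller than the filter window", "nif_error_shape")
  out <- matrix(0, m, n)
  for (i in seq_len(m)) out[i, i:(i + 2L * r)] <- k
  out
}

filt2_valid <- function(x, k) {
  ty <- valid_band_matrix(nrow(x), k)
  tx <- valid_band_matrix(ncol(x), k)
  ty %*% x %*% t(tx)
}

ssim_plane <- function(x, y, data_range, sigma, radius, k1, k2) {
  w <- gaussian_window_1d(sigma, radius)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  ux <- filt2_valid(x, w)
  uy <- filt2_valid(y, w)
  uxx <- filt2_valid(x * x, w)
  uyy <- filt2_valid(y * y, w)
  uxy <- filt2_valid(x * y, w)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  cxy <- uxy - ux * uy
  s <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Structural similarity index
#'
#' Windowed SSIM with an 11x11 Gaussian window (sigma 1.5) and the standard
#' stabilizers k1 = 0.01, k2 = 0.03, averaged over window positions. Arrays
#' with more than two dimensions are scored as the mean over their Y-X
#' planes.
#'
#' @param a,b arrays or [nif_image]s of equal shape.
#' @param data_range signal range; defaults to the dtype maximum of `a`.
#' @param sigma Gaussian window sigma.
#' @param window window side length (odd).
#' @param k1,k2 stabilizing constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = NULL, sigma = 1.5, window = 11L,
                 k1 = 0.01, k2 = 0.03) {
  if (is.null(data_range)) data_range <- metric_data_range(a)
  x <- as_image_array(a); y <- as_image_array(b)
  if (is.null(dim(x))) dim(x) <- c(1L, length(x))
  if (is.null(dim(y))) dim(y) <- c(1L, length(y))
  if (!identical(dim(x), dim(y))) nif_stop("shape mismatch", "nif_error_shape")
  radius <- (as.integer(window) - 1L) %/% 2L
  d <- length(dim(x))
  if (any(tail(dim(x), 2L) < window))
    nif_stop("image smaller than the SSIM window", "nif_error_shape")
  x <- array(as.numeric(x), dim(x))
  y <- array(as.numeric(y), dim(y))
  if (d == 2L)
    return(ssim_plane(x, y, data_range, sigma, radius, k1, k2))
  ny <- dim(x)[d - 1L]; nx <- dim(x)[d]
  nplanes <- prod(dim(x)) / (ny * nx)
  fx <- flatten_rm(x); fy <- flatten_rm(y)
  vals <- vapply(seq_len(nplanes), function(i) {
    sel <- ((i - 1) * ny * nx + 1):(i * ny * nx)
    ssim_plane(matrix(fx[sel], ny, nx, byrow = TRUE),
               matrix(fy[sel], ny, nx, byrow = TRUE),
               data_range, sigma, radius, k1, k2)
  }, numeric(1))
  mean(vals)
}
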