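# Seeded synthetic microscopy generator. Every generator is a pure function
# of its arguments plus the seed; fixtures for the whole test suite come
# from here, emulating (a) DNA-stained nucleus volumes, (b) striped
# filament patterns, (c) partially colocalized multichannel fields and
# (d) shot-plus-read noise at low illumination.

# Band-limited positive texture in [0,1]: Gaussian-smoothed white noise,
# rescaled. Uses the current RNG stream.
smooth_noise <- function(shape, sigma) {
  x <- array(rnorm(prod(shape)), shape)
  x <- smooth_gauss(x, sigma)
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else array(0.5, shape)
}

#' Synthetic 3D nucleus volume
#'
#' Ellipsoidal bright bodies with smooth internal texture on a dim
#' background, mimicking DNA-stained confocal stacks. Nuclei are placed
#' with rejection sampling so they do not overlap; at half-maximum
#' threshold the volume has exactly `n_nuclei` connected components.
#'
#' @param shape 3D extents (Z, Y, X).
#' @param n_nuclei number of nuclei (>= 0).
#' @param texture_amp relative amplitude of the internal texture, in [0, 1].
#' @param seed integer seed.
#' @return a u16 [nif_image] with axes ZYX.
#' @export
make_nuclei_volume <- function(shape = c(32L, 48L, 48L), n_nuclei = 4L,
                               texture_amp = 0.25, seed = 0L) {
  if (length(shape) != 3L) nif_stop("shape must be 3D (Z, Y, X)", "nif_error_shape")
  if (n_nuclei < 0) nif_stop("n_nuclei must be >= 0", "nif_error_range")
  rmax <- min(shape) / 4
  if (n_nuclei > 0 && 2 * rmax > min(shape))
    nif_stop("nuclei larger than the volume", "nif_error_shape")
  with_seed(seed, {
    bg <- 1200 + 600 * smooth_noise(shape, 3)
    vol <- bg
    if (n_nuclei > 0) {
      centers <- matrix(0, 0, 3)
      radii <- numeric(0)
      tries <- 0L
      while (nrow(centers) < n_nuclei) {
        tries <- tries + 1L
        if (tries > 5000L)
          nif_stop("cannot place non-overlapping nuclei in this volume",
                   "nif_error_shape")
        r <- runif(1, 0.55, 1) * rmax
        ctr <- vapply(1:3, function(d) runif(1, r + 1, shape[d] - r - 1),
                      numeric(1))
        ok <- TRUE
        if (nrow(centers) > 0) {
          dist <- sqrt(colSums((t(centers) - ctr)^2))
          ok <- all(dist > (radii + r) * 1.15 + 2)
        }
        if (ok) { centers <- rbind(centers, ctr); radii <- c(radii, r) }
      }
      ax <- lapply(1:3, function(d) seq_len(shape[d]))
      tex <- smooth_noise(shape, 2)
      for (i in seq_len(n_nuclei)) {
        dz <- (ax[[1]] - centers[i, 1]) / radii[i]
        dy <- (ax[[2]] - centers[i, 2]) / (radii[i] * runif(1, 0.8, 1.1))
        dx <- (ax[[3]] - centers[i, 3]) / (radii[i] * runif(1, 0.8, 1.1))
        d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
        body <- 1 / (1 + exp((sqrt(d2) - 1) / 0.08))
        vol <- vol + body * 26000 * (1 + texture_amp * (tex - 0.5))
      }
    }
    vol <- pmin(pmax(vol, 0), 65535)
    v <- round(vol); storage.mode(v) <- "integer"
    nif_image(array(v, shape), c("Z", "Y", "X"), "u16")
  })
}

#' Synthetic striped filament image
#'
#' Curvilinear fibers with a periodic intensity modulation along their
#' length (period `stripe_period` pixels), on a dim background, emulating
#' sarcomere-like striped filament morphology.
#'
#' @param shape 2D (Y, X) or 3D (Z, Y, X) extents.
#' @param n_fibers number of fibers.
#' @param stripe_period modulation period along the fiber, in pixels (>= 2).
#' @param seed integer seed.
#' @return a u16 [nif_image].
#' @export
make_filament_image <- function(shape = c(96L, 96L), n_fibers = 6L,
                                stripe_period = 8, seed = 0L) {
  d <- length(shape)
  if (!d %in% c(2L, 3L)) nif_stop("shape must be 2D or 3D", "nif_error_shape")
  if (stripe_period < 2) nif_stop("stripe_period must be >= 2 px", "nif_error_range")
  with_seed(seed, {
    acc <- array(0, shape)
    paths <- list()
    if (n_fibers > 0) {
      len <- 0.8 * max(shape)
      step <- 0.5
      nsteps <- ceiling(len / step)
      for (fb in seq_len(n_fibers)) {
        pos <- vapply(seq_len(d), function(ax) runif(1, 0.15, 0.85) * shape[ax],
                      numeric(1))
        theta <- runif(1, 0, 2 * pi)
        dirv <- if (d == 2L) c(cos(theta), sin(theta))
                else { phi <- runif(1, -0.3, 0.3); c(sin(phi), cos(phi) * cos(theta), cos(phi) * sin(theta)) }
        curv <- rnorm(nsteps, sd = 0.012)
        arclen <- 0
        trail <- matrix(NA_real_, nsteps, d)
        for (st in seq_len(nsteps)) {
          if (d == 2L) {
            a <- atan2(dirv[2], dirv[1]) + curv[st]
            dirv <- c(cos(a), sin(a))
          } else {
            a <- atan2(dirv[3], dirv[2]) + curv[st]
            dirv <- c(dirv[1], cos(a) * sqrt(1 - dirv[1]^2),
                      sin(a) * sqrt(1 - dirv[1]^2))
          }
          pos <- pos + step * dirv
          if (any(pos < 2) || any(pos > shape - 1)) break
          arclen <- arclen + step
          amp <- 0.6 + 0.4 * cos(2 * pi * arclen / stripe_period)
          # normalize by the splat line density so the tube center tracks
          # `amp` instead of saturating
          acc <- splat_gauss(acc, pos, amp * step / (1.1 * sqrt(2 * pi)), 1.1)
          trail[st, ] <- pos
        }
        paths[[fb]] <- trail[stats::complete.cases(trail), , drop = FALSE]
      }
    }
    img <- 900 + 500 * smooth_noise(shape, 3) + 24000 * pmin(acc, 1.4)
    img <- pmin(pmax(img, 0), 65535)
    v <- round(img); storage.mode(v) <- "integer"
    out <- nif_image(array(v, shape),
                     if (d == 2L) c("Y", "X") else c("Z", "Y", "X"), "u16")
    # fiber center-line samples (one row per 0.5 px arclength step), so
    # callers can measure properties along the fibers
    attr(out, "fiber_paths") <- paths
    out
  })
}

# Adds a small Gaussian splat at a continuous position (tube profile).
splat_gauss <- function(acc, pos, amp, sigma) {
  d <- length(pos)
  r <- 3L
  lo <- pmax(floor(pos) - r, 1)
  hi <- pmin(floor(pos) + r, dim(acc))
  if (any(hi < lo)) return(acc)
  ax <- lapply(seq_len(d), function(k) lo[k]:hi[k])
  if (d == 2L) {
    d2 <- outer((ax[[1]] - pos[1])^2, (ax[[2]] - pos[2])^2, `+`)
    acc[ax[[1]], ax[[2]]] <- acc[ax[[1]], ax[[2]]] +
      amp * exp(-d2 / (2 * sigma^2))
  } else {
    d2 <- outer(outer((ax[[1]] - pos[1])^2, (ax[[2]] - pos[2])^2, `+`),
                (ax[[3]] - pos[3])^2, `+`)
    acc[ax[[1]], ax[[2]], ax[[3]]] <- acc[ax[[1]], ax[[2]], ax[[3]]] +
      amp * exp(-d2 / (2 * sigma^2))
  }
  acc
}

#' Synthetic multichannel image with tunable colocalization
#'
#' Channel 1 is a structure map; every further channel mixes a fresh
#' structure with channel 1 at weight `colocalization`, so the expected
#' Pearson correlation between channels rises with the weight.
#'
#' @param shape spatial extents, 2D (Y, X) or 3D (Z, Y, X).
#' @param n_channels number of channels (>= 1).
#' @param colocalization mixing weight in [0, 1].
#' @param seed integer seed.
#' @return a u16 [nif_image] with a leading C axis.
#' @export
make_multichannel <- function(shape = c(96L, 96L), n_channels = 3L,
                              colocalization = 0.5, seed = 0L) {
  if (n_channels < 1) nif_stop("n_channels must be >= 1", "nif_error_range")
  if (colocalization < 0 || colocalization > 1)
    nif_stop("colocalization must be in [0, 1]", "nif_error_range")
  with_seed(seed, {
    base <- smooth_noise(shape, 3)
    chans <- vector("list", n_channels)
    chans[[1]] <- base
    if (n_channels > 1) {
      for (j in 2:n_channels) {
        fresh <- smooth_noise(shape, 3)
        chans[[j]] <- colocalization * base + (1 - colocalization) * fresh
      }
    }
    arr <- array(0, c(n_channels, shape))
    d <- length(shape)
    for (j in seq_len(n_channels)) {
      idx <- c(list(j), rep(list(quote(expr = )), d))
      arr <- do.call(`[<-`, c(list(arr), idx, list(chans[[j]] * 52000 + 800)))
    }
    v <- round(arr); storage.mode(v) <- "integer"
    nif_image(v, c("C", if (d == 2L) c("Y", "X") else c("Z", "Y", "X")), "u16")
  })
}

#' Add shot and read noise (low-illumination model)
#'
#' Pixel values are scaled into expected photon counts (`photon_scale`
#' photons at the dtype maximum), Poisson-sampled, rescaled, and Gaussian
#' read noise is added; the result is clipped to the dtype range. Lower
#' `photon_scale` means noisier output.
#'
#' @param img a [nif_image] (integer dtype).
#' @param photon_scale expected photons at full scale (> 0).
#' @param read_sigma read-noise standard deviation in intensity units.
#' @param seed integer seed.
#' @return a [nif_image] with the same shape and dtype.
#' @export
add_low_laser_noise <- function(img, photon_scale = 100, read_sigma = 50,
                                seed = 0L) {
  if (photon_scale <= 0) nif_stop("photon_scale must be > 0", "nif_error_range")
  info <- dtype_info(img$dtype_code)
  vmax <- if (is.finite(info$max)) info$max else max(img$data)
  with_seed(seed, {
    lam <- pmax(img$data / vmax * photon_scale, 0)
    shot <- array(rpois(length(lam), lam), dim(lam)) / photon_scale * vmax
    out <- shot + rnorm(length(lam), sd = read_sigma)
    out <- pmin(pmax(out, info$min), info$max)
    if (info$integer) { out <- round(out); storage.mode(out) <- "integer" }
    nif_image(array(out, dim(lam)), img$axes, img$dtype_code)
  })
}
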