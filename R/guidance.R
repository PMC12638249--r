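# Task-guided training losses.
#
# Segmentation guidance keeps thin structures segmentable after compression:
# the training loss adds 1 - softIoU between a differentiable soft
# segmentation of the decoded image and a fixed (stop-gradient) soft mask of
# the original. Evaluation uses the hard reference segmenter. Perceptual
# guidance compares random patches of the reconstruction against a clean
# reference through a layered feature network (useful when the input itself
# is noisy).
#
# All convolutions in the differentiable path are circular, so every linear
# operator is exactly self-adjoint (symmetric kernels) and the hand-written
# gradients are exact to float precision.

.conv_cache <- new.env(parent = emptyenv())

gauss_taps <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Scale-normalized second-derivative-of-Gaussian taps (zero-sum).
gauss_d2_taps <- function(sigma) {
  radius <- max(2L, ceiling(3 * sigma))
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- g * (x^2 - sigma^2) / sigma^4
  k - mean(k)
}

circ_mat <- function(n, taps) {
  key <- paste(n, paste(signif(taps, 12), collapse = ","), sep = "|")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(taps) - 1L) %/% 2L
  cm <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in (-r):r) {
    j <- ((i - 1L + t) %% n) + 1L
    cm[cbind(i, j)] <- cm[cbind(i, j)] + taps[t + r + 1L]
  }
  .conv_cache[[key]] <- cm
  cm
}

# Apply a circulant filter along one axis of an N-D array.
conv_axis_circ <- function(arr, taps, axis) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nd <- length(d)
  cm <- circ_mat(d[axis], taps)
  if (nd == 1L) return(as.vector(cm %*% arr))
  perm <- c(axis, seq_len(nd)[-axis])
  m <- matrix(aperm(arr, perm), d[axis])
  m <- cm %*% m
  aperm(array(m, d[perm]), order(perm))
}

smooth_gauss <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  taps <- gauss_taps(sigma)
  for (ax in seq_along(dim(arr))) arr <- conv_axis_circ(arr, taps, ax)
  arr
}

# Bright-ridge/structure response: negative scale-normalized Laplacian of
# Gaussian, positive on bright lines and bodies. Linear in the image.
ridge_response <- function(arr, scale) {
  g <- gauss_taps(scale)
  g2 <- gauss_d2_taps(scale)
  d <- length(dim(arr))
  out <- array(0, dim(arr))
  for (ax in seq_len(d)) {
    term <- conv_axis_circ(arr, g2, ax)
    for (other in seq_len(d)[-ax]) term <- conv_axis_circ(term, g, other)
    out <- out + term
  }
  -scale^2 * out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Segmentation pipeline parameters
#'
#' Defaults follow the published filament-segmentation workflow: contrast
#' clipping at mean - 1.5 sd / mean + 10.5 sd, Gaussian smoothing sigma 1,
#' ridge filter scale 1 with response cutoff 0.01, and removal of objects
#' under 20 pixels.
#'
#' @param contrast_bounds clip offsets below/above the mean, in sd units.
#' @param smoothing_sigma Gaussian smoothing sigma (pixels).
#' @param filament_scales pair (ridge scale, response cutoff).
#' @param min_object_size components smaller than this are removed.
#' @param soft_threshold_temp sigmoid temperature of the differentiable
#'   surrogate; the soft mask converges to the hard threshold as it tends
#'   to zero. The default (0.1) is deliberately warm: it keeps the sigmoid
#'   unsaturated over most of the ridge-response range, so training
#'   gradients stay dense instead of collapsing onto the decision boundary.
#' @return a `nif_seg_params` list.
#' @export
seg_params <- function(contrast_bounds = c(1.5, 10.5), smoothing_sigma = 1,
                       filament_scales = c(1, 0.01), min_object_size = 20L,
                       soft_threshold_temp = 0.1) {
  if (min_object_size < 0) nif_stop("min_object_size must be >= 0", "nif_error_range")
  structure(list(contrast_bounds = contrast_bounds,
                 smoothing_sigma = smoothing_sigma,
                 filament_scales = filament_scales,
                 min_object_size = as.integer(min_object_size),
                 soft_threshold_temp = soft_threshold_temp),
            class = "nif_seg_params")
}

#' Intersection over union of two masks
#'
#' For binary masks, `|A ∩ B| / |A ∪ B|`; soft masks use
#' `sum(a*b) / sum(a + b - a*b)`, which coincides with the hard ratio on
#' binary inputs. Two empty masks have IoU 1 (perfect agreement on absence).
#'
#' @param mask_a,mask_b arrays with values in `[0, 1]`, equal shapes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  a <- as_image_array(mask_a); b <- as_image_array(mask_b)
  if (length(a) != length(b) ||
      (!is.null(dim(a)) && !is.null(dim(b)) && !identical(dim(a), dim(b))))
    nif_stop("shape mismatch", "nif_error_shape")
  a <- as.numeric(a); b <- as.numeric(b)
  inter <- sum(a * b)
  union <- sum(a + b - a * b)
  if (union == 0) return(1)
  inter / union
}

#' Reference segmentation of filamentous/bright structures
#'
#' Deterministic hard pipeline: contrast clipping (mean - k1 sd to
#' mean + k2 sd, rescaled to [0,1]) -> Gaussian smoothing -> bright-ridge
#' response at the configured scale, thresholded at the cutoff -> removal of
#' connected components smaller than `min_object_size` (4-/6-connectivity).
#'
#' @param img 2D or 3D single-channel [nif_image] or array.
#' @param p a [seg_params()].
#' @return logical array: the binary mask.
#' @export
reference_segment <- function(img, p = seg_params()) {
  x <- as_image_array(img)
  if (is.null(dim(x))) dim(x) <- length(x)
  if (length(dim(x)) > 3L)
    nif_stop("reference_segment supports 2D/3D images", "nif_error_shape")
  x <- array(as.numeric(x), dim(x))
  m <- mean(x); s <- sd(x)
  lo <- m - p$contrast_bounds[1] * s
  hi <- m + p$contrast_bounds[2] * s
  x01 <- if (hi > lo) pmin(pmax((x - lo) / (hi - lo), 0), 1) else array(0, dim(x))
  x01 <- array(x01, dim(x))
  sm <- smooth_gauss(x01, p$smoothing_sigma)
  r <- ridge_response(sm, p$filament_scales[1])
  mask <- r > p$filament_scales[2]
  if (p$min_object_size > 0 && any(mask)) {
    lab <- .label_components(mask, as.integer(dim(mask)))
    sizes <- tabulate(lab)
    keep <- which(sizes >= p$min_object_size)
    mask <- array(lab %in% keep, dim(mask))
  }
  mask
}

# The frozen affine contrast map the hard pipeline would derive from `x`:
# clip window mean - k1 sd .. mean + k2 sd, rescaled to [0, 1].
contrast_window <- function(x, bounds) {
  m <- mean(x); s <- sd(x)
  c(lo = m - bounds[1] * s, hi = m + bounds[2] * s)
}

#' Differentiable soft segmentation
#'
#' Smooth surrogate of [reference_segment()]: an affine contrast map, Gaussian
#' smoothing, the same ridge response, then a sigmoid soft threshold
#' `sigmoid((r - cutoff) / temp)`. As the temperature tends to zero the soft
#' mask converges pointwise (away from the decision boundary) to the hard
#' threshold. Two deliberate smoothings keep it differentiable and stable as
#' an optimization target: the contrast window is a fixed affine map (by
#' default derived from the input itself; during training it is frozen from
#' the original image so gradients cannot warp the global statistics the
#' hard segmenter adapts to), and no hard clipping is applied.
#'
#' @param img_norm array with values in `[0, 1]`.
#' @param p a [seg_params()]; `soft_threshold_temp` must be positive.
#' @param contrast optional `c(lo, hi)` clip window in input units; default
#'   derives the window from `img_norm` with `p$contrast_bounds`.
#' @return array of soft mask values in `(0, 1)`.
#' @export
soft_segment <- function(img_norm, p = seg_params(), contrast = NULL) {
  if (p$soft_threshold_temp <= 0)
    nif_stop("soft_threshold_temp must be > 0", "nif_error_range")
  x <- as_image_array(img_norm)
  if (is.null(dim(x))) dim(x) <- length(x)
  x <- array(as.numeric(x), dim(x))
  if (is.null(contrast)) contrast <- contrast_window(x, p$contrast_bounds)
  x <- (x - contrast[1]) / max(contrast[2] - contrast[1], 1e-12)
  sm <- smooth_gauss(x, p$smoothing_sigma)
  r <- ridge_response(sm, p$filament_scales[1])
  sigmoid((r - p$filament_scales[2]) / p$soft_threshold_temp)
}

#' Segmentation-preserving loss
#'
#' `1 - softIoU(soft_segment(decoded), mask(original))`, in `[0, 1]`. The
#' original's mask is treated as a constant (no gradient flows into it).
#'
#' @param decoded_patch,original_patch arrays in `[0, 1]`, equal shapes.
#' @param p a [seg_params()].
#' @return scalar loss.
#' @export
segmentation_loss <- function(decoded_patch, original_patch, p = seg_params()) {
  segmentation_loss_grad(decoded_patch, original_patch, p, want_grad = FALSE)$loss
}

# Loss plus its exact gradient with respect to the decoded image. The linear
# part (smooth + ridge) is self-adjoint and its factors commute, so the
# adjoint is the same pipeline applied to the upstream gradient.
segmentation_loss_grad <- function(decoded_patch, original_patch,
                                   p = seg_params(), target = NULL,
                                   contrast = NULL, want_grad = TRUE) {
  x <- as_image_array(decoded_patch)
  if (is.null(dim(x))) dim(x) <- length(x)
  x <- array(as.numeric(x), dim(x))
  if (is.null(target)) {
    o <- as_image_array(original_patch)
    if (!identical(dim(array(o, dim(x))), dim(x)) && length(o) != length(x))
      nif_stop("shape mismatch", "nif_error_shape")
    o <- array(as.numeric(o), dim(x))
    if (is.null(contrast)) contrast <- contrast_window(o, p$contrast_bounds)
    target <- soft_segment(o, p, contrast = contrast)
  }
  if (is.null(contrast))
    nif_stop("a frozen contrast window is required with a precomputed target",
             "nif_error_range")
  if (length(target) != length(x)) nif_stop("shape mismatch", "nif_error_shape")
  s <- soft_segment(x, p, contrast = contrast)
  m <- target
  inter <- sum(s * m)
  union <- sum(s + m - s * m)
  loss <- if (union == 0) 0 else 1 - inter / union
  if (!want_grad) return(list(loss = loss))
  if (union == 0) return(list(loss = loss, grad = array(0, dim(x))))
  # d(1 - I/U)/dS = -(m*U - I*(1-m)) / U^2
  dS <- -(m * union - inter * (1 - m)) / union^2
  dr <- dS * s * (1 - s) / p$soft_threshold_temp
  g <- ridge_response(dr, p$filament_scales[1])
  g <- smooth_gauss(g, p$smoothing_sigma)
  list(loss = loss,
       grad = g / max(contrast[2] - contrast[1], 1e-12))
}

## ---- perceptual guidance ----------------------------------------------

#' Perceptual-loss parameters
#'
#' @param patch_size side length of the square patches compared.
#' @param layer_weights optional list of per-channel scale vectors, one per
#'   feature layer (default: unit weights).
#' @param feature_net_id `"toy"` (seeded built-in convolutional stack) or
#'   `"identity"` (features are the raw pixels, reducing the loss to MSE).
#' @param feature_net_seed seed for the built-in feature network.
#' @return a `nif_perc_params` list.
#' @export
perc_params <- function(patch_size = 16L, layer_weights = NULL,
                        feature_net_id = "toy", feature_net_seed = 0L) {
  structure(list(patch_size = as.integer(patch_size),
                 layer_weights = layer_weights,
                 feature_net_id = feature_net_id,
                 feature_net_seed = as.integer(feature_net_seed)),
            class = "nif_perc_params")
}

#' Seeded convolutional feature network
#'
#' A fixed, deterministic 3-layer stack of 3x3 convolutions with ReLU
#' activations. Not pretrained: it provides a reproducible default feature
#' space; externally trained networks can be supplied through the same
#' structure (a list of `kxkxCinxCout` weight arrays).
#'
#' @param seed integer seed.
#' @param channels output channels per layer.
#' @param kernel odd kernel side length.
#' @return object of class `nif_feature_net`.
#' @export
feature_net <- function(seed = 0L, channels = c(8L, 8L, 8L), kernel = 3L) {
  cin <- 1L
  weights <- with_seed(seed, lapply(channels, function(cout) {
    w <- array(rnorm(kernel * kernel * cin * cout,
                     sd = sqrt(2 / (kernel * kernel * cin))),
               dim = c(kernel, kernel, cin, cout))
    cin <<- cout
    w
  }))
  structure(list(weights = weights, kernel = as.integer(kernel)),
            class = "nif_feature_net")
}

#' Identity feature "network"
#'
#' A single layer whose features are the raw pixels; the perceptual loss
#' then equals the mean squared pixel difference.
#' @return object of class `nif_feature_net`.
#' @export
identity_feature_net <- function() {
  structure(list(weights = NULL, kernel = 1L, identity = TRUE),
            class = "nif_feature_net")
}

shift2_zero <- function(m, du, dv) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + du):min(h, h + du)
  xs <- max(1, 1 + dv):min(w, w + dv)
  if (length(ys) && length(xs)) out[ys - du, xs - dv] <- m[ys, xs]
  out
}

conv2d_same <- function(x, w) {
  # x: H x W x Cin, w: k x k x Cin x Cout, zero padding
  k <- dim(w)[1]; r <- (k - 1L) %/% 2L
  cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  out <- array(0, c(h, wd, cout))
  for (u in -r:r) for (v in -r:r) for (ci in seq_len(cin)) {
    sh <- shift2_zero(x[, , ci], u, v)
    for (co in seq_len(cout))
      out[, , co] <- out[, , co] + sh * w[u + r + 1L, v + r + 1L, ci, co]
  }
  out
}

conv2d_adjoint <- function(g, w) {
  k <- dim(w)[1]; r <- (k - 1L) %/% 2L
  cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(g)[1]; wd <- dim(g)[2]
  out <- array(0, c(h, wd, cin))
  for (u in -r:r) for (v in -r:r) for (co in seq_len(cout)) {
    sh <- shift2_zero(g[, , co], -u, -v)
    for (ci in seq_len(cin))
      out[, , ci] <- out[, , ci] + sh * w[u + r + 1L, v + r + 1L, ci, co]
  }
  out
}

feature_forward <- function(net, x, cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (isTRUE(net$identity))
    return(list(features = list(x), pre = list(x), input = x))
  feats <- vector("list", length(net$weights))
  pre <- vector("list", length(net$weights))
  h <- x
  for (i in seq_along(net$weights)) {
    z <- conv2d_same(h, net$weights[[i]])
    pre[[i]] <- z
    h <- pmax(z, 0)
    feats[[i]] <- h
  }
  list(features = feats, pre = pre, input = x)
}

#' Layer-weighted perceptual patch loss
#'
#' Sum over feature layers of the spatially averaged squared channel-weighted
#' feature difference between the reconstructed and reference patches:
#' zero iff all feature maps agree; with identity features it reduces to the
#' mean squared pixel difference.
#'
#' @param patch_hat,patch_ref equal-shape numeric matrices.
#' @param net a [feature_net()] or [identity_feature_net()].
#' @param w optional list of per-channel weight vectors, one per layer.
#' @return scalar loss, `>= 0`.
#' @export
perceptual_loss <- function(patch_hat, patch_ref, net = feature_net(), w = NULL) {
  perceptual_loss_grad(patch_hat, patch_ref, net, w, want_grad = FALSE)$loss
}

perceptual_loss_grad <- function(patch_hat, patch_ref, net = feature_net(),
                                 w = NULL, want_grad = TRUE) {
  if (!identical(dim(patch_hat), dim(patch_ref)))
    nif_stop("patch shape mismatch", "nif_error_shape")
  fh <- feature_forward(net, patch_hat)
  fr <- feature_forward(net, patch_ref)
  nl <- length(fh$features)
  if (!is.null(w)) {
    if (length(w) != nl)
      nif_stop("layer weight count does not match feature layers", "nif_error_shape")
  } else {
    w <- lapply(fh$features, function(f) rep(1, dim(f)[3]))
  }
  loss <- 0
  dfeat <- vector("list", nl)
  for (i in seq_len(nl)) {
    d <- fh$features[[i]] - fr$features[[i]]
    wi <- w[[i]]
    wd <- sweep(d, 3L, wi, `*`)
    hw <- prod(dim(d)[1:2])
    loss <- loss + sum(wd^2) / hw
    if (want_grad) dfeat[[i]] <- sweep(wd, 3L, wi, `*`) * (2 / hw)
  }
  if (!want_grad) return(list(loss = loss))
  if (isTRUE(net$identity)) {
    g <- dfeat[[1]]
    return(list(loss = loss, grad = array(g, dim(patch_hat))))
  }
  g <- array(0, dim(fh$features[[nl]]))
  for (i in rev(seq_len(nl))) {
    g <- g + dfeat[[i]]
    g <- g * (fh$pre[[i]] > 0)
    g <- conv2d_adjoint(g, net$weights[[i]])
  }
  list(loss = loss, grad = array(g, dim(patch_hat)))
}

#' Sample a reconstruction patch and a reference patch
#'
#' Draws seeded uniform top-left corners, independently for the two sources,
#' over every valid position; the reconstruction patch is rendered by
#' `decoded_provider` (so gradients can flow into the model), the reference
#' patch is a constant crop.
#'
#' @param decoded_provider `function(y0, x0, size)` returning the rendered
#'   `size x size` patch at the given 0-based top-left corner.
#' @param reference_img numeric matrix (the clean reference plane).
#' @param p a [perc_params()].
#' @param seed integer seed.
#' @return list with `patch_hat`, `patch_ref`, `loc_hat`, `loc_ref`
#'   (0-based `(y, x)` corners).
#' @export
sample_guided_patches <- function(decoded_provider, reference_img, p, seed) {
  ps <- p$patch_size
  h <- nrow(reference_img); wd <- ncol(reference_img)
  if (ps > h || ps > wd)
    nif_stop("patch larger than source", "nif_error_shape")
  with_seed(seed, {
    loc_hat <- c(sample.int(h - ps + 1L, 1L), sample.int(wd - ps + 1L, 1L)) - 1L
    loc_ref <- c(sample.int(h - ps + 1L, 1L), sample.int(wd - ps + 1L, 1L)) - 1L
    list(
      patch_hat = decoded_provider(loc_hat[1], loc_hat[2], ps),
      patch_ref = reference_img[loc_ref[1] + seq_len(ps),
                                loc_ref[2] + seq_len(ps), drop = FALSE],
      loc_hat = loc_hat, loc_ref = loc_ref
    )
  })
}

## ---- trainer integration ----------------------------------------------

#' Guidance configuration for the trainer
#'
#' @param mode `"none"`, `"segmentation"` or `"perceptual"`.
#' @param weight non-negative guidance weight; the total training loss is
#'   `mse + weight * guidance`. Weight 0 reproduces the unguided trainer
#'   exactly.
#' @param seg_params a [seg_params()].
#' @param perc_params a [perc_params()].
#' @param apply_every apply the guidance term every this many steps.
#' @param reference clean reference [nif_image] (perceptual mode).
#' @return a `nif_guidance` list.
#' @export
guidance_config <- function(mode = c("none", "segmentation", "perceptual"),
                            weight = 0.1, seg_params = NULL,
                            perc_params = NULL, apply_every = 1L,
                            reference = NULL) {
  mode <- match.arg(mode)
  if (weight < 0) nif_stop("weight must be >= 0", "nif_error_range")
  structure(list(mode = mode, weight = weight,
                 seg_params = seg_params %||% inif::seg_params(),
                 perc_params = perc_params %||% inif::perc_params(),
                 apply_every = as.integer(apply_every),
                 reference = reference),
            class = "nif_guidance")
}

guidance_meta <- function(guid) {
  if (is.null(guid) || guid$mode == "none" || guid$weight == 0) return(NULL)
  list(guidance = list(mode = guid$mode, weight = guid$weight))
}

# Builds the per-step guidance gradient closure used by train_engine().
# `norm_img` is the normalized (0..100) image being compressed.
build_guidance_context <- function(guid, norm_img, cfg) {
  if (is.null(guid) || guid$mode == "none" || guid$weight == 0) return(NULL)
  x01 <- norm_img$data / (100)
  shape <- dim(x01)
  d <- length(shape)
  if (!d %in% c(2L, 3L))
    nif_stop("guidance supports 2D/3D images", "nif_error_shape")
  nplanes <- if (d == 2L) 1L else shape[1]
  ny <- shape[d - 1L]; nx <- shape[d]

  plane_coords <- function(z) {
    if (d == 2L) {
      make_grid(shape)$coords
    } else {
      idx <- subgrid_indices(list(z - 1L, 0:(ny - 1L), 0:(nx - 1L)))
      coords_for_indices(shape, idx)
    }
  }
  coord_cache <- new.env(parent = emptyenv())
  get_coords <- function(z) {
    key <- as.character(z)
    hit <- coord_cache[[key]]
    if (is.null(hit)) {
      hit <- plane_coords(z)
      coord_cache[[key]] <- hit
    }
    hit
  }
  plane01 <- function(z) {
    if (d == 2L) x01
    else matrix(flatten_rm(x01)[((z - 1) * ny * nx + 1):(z * ny * nx)],
                ny, nx, byrow = TRUE)
  }

  if (guid$mode == "segmentation") {
    p <- guid$seg_params
    # Targets are planes of the hard reference mask of the original volume:
    # that is exactly what downstream evaluation measures, and it anchors
    # training better than the original's own soft mask. The decoded branch
    # stays soft (differentiable), with the contrast window frozen from the
    # original plane.
    ref_mask <- reference_segment(x01, p)
    target_cache <- new.env(parent = emptyenv())
    get_target <- function(z) {
      key <- as.character(z)
      hit <- target_cache[[key]]
      if (is.null(hit)) {
        pl <- plane01(z)
        mk <- if (d == 2L) ref_mask
              else matrix(flatten_rm(ref_mask)[((z - 1) * ny * nx + 1):
                                               (z * ny * nx)],
                          ny, nx, byrow = TRUE)
        hit <- list(mask = mk * 1.0,
                    contrast = contrast_window(pl, p$contrast_bounds))
        target_cache[[key]] <- hit
      }
      hit
    }
    grad_fn <- function(model, step) {
      if (step %% guid$apply_every != 0L) return(NULL)
      z <- if (nplanes > 1L) sample.int(nplanes, 1L) else 1L
      coords <- get_coords(z)
      cache <- model_forward(model, coords, fast = TRUE, cache = TRUE)
      pred01 <- matrix(cache$out[, 1L] / 100, ny, nx, byrow = TRUE)
      tg <- get_target(z)
      sl <- segmentation_loss_grad(pred01, NULL, p, target = tg$mask,
                                   contrast = tg$contrast)
      dout <- matrix(as.vector(t(sl$grad)) / 100, ncol = 1L)
      g <- pack_grads(model, model_backward(model, cache, dout))
      list(loss = sl$loss, grad = g)
    }
  } else {
    if (is.null(guid$reference))
      nif_stop("perceptual guidance needs a clean reference image", "nif_error_range")
    p <- guid$perc_params
    net <- if (p$feature_net_id == "identity") identity_feature_net()
           else feature_net(p$feature_net_seed)
    ref01 <- minmax_normalize(guid$reference)$image$data / 100
    refshape <- dim(ref01)
    ps <- p$patch_size
    grad_fn <- function(model, step) {
      if (step %% guid$apply_every != 0L) return(NULL)
      z <- if (nplanes > 1L) sample.int(nplanes, 1L) else 1L
      zr <- if (length(refshape) == 3L) sample.int(refshape[1], 1L) else 1L
      y0 <- sample.int(ny - ps + 1L, 1L) - 1L
      x0 <- sample.int(nx - ps + 1L, 1L) - 1L
      yr <- sample.int(refshape[length(refshape) - 1L] - ps + 1L, 1L) - 1L
      xr <- sample.int(refshape[length(refshape)] - ps + 1L, 1L) - 1L
      idx <- if (d == 2L)
        subgrid_indices(list(y0 + 0:(ps - 1L), x0 + 0:(ps - 1L)))
      else
        subgrid_indices(list(z - 1L, y0 + 0:(ps - 1L), x0 + 0:(ps - 1L)))
      coords <- coords_for_indices(shape, idx)
      cache <- model_forward(model, coords, fast = TRUE, cache = TRUE)
      hat01 <- matrix(cache$out[, 1L] / 100, ps, ps, byrow = TRUE)
      refplane <- if (length(refshape) == 3L)
        matrix(flatten_rm(ref01)[((zr - 1) * prod(refshape[2:3]) + 1):
                                 (zr * prod(refshape[2:3]))],
               refshape[2], refshape[3], byrow = TRUE)
      else ref01
      refpatch <- refplane[yr + seq_len(ps), xr + seq_len(ps), drop = FALSE]
      pl <- perceptual_loss_grad(hat01, refpatch, net, p$layer_weights)
      gmat <- matrix(pl$grad, ps, ps)
      dout <- matrix(as.vector(t(gmat)) / 100, ncol = 1L)
      g <- pack_grads(model, model_backward(model, cache, dout))
      list(loss = pl$loss, grad = g)
    }
  }
  list(weight = guid$weight, grad_fn = grad_fn)
}
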