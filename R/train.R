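# The compression loop: fit the coordinate network to normalized pixel
# values under the byte budget chosen by the sizing module.

#' Mean squared error
#'
#' @param pred,target equal-length numeric vectors/arrays.
#' @return mean of squared differences.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) == 0) nif_stop("empty input", "nif_error_empty")
  if (length(pred) != length(target))
    nif_stop("length mismatch", "nif_error_shape")
  mean((as.numeric(pred) - as.numeric(target))^2)
}

#' Compression configuration
#'
#' @param target_cr requested compression ratio (> 1).
#' @param steps optimization steps (default 5000).
#' @param batch_points grid points per step (default 65536; the full grid is
#'   used when it is smaller). Each epoch is a seeded permutation of the grid
#'   consumed batch by batch, reshuffled when exhausted.
#' @param seed integer seed driving initialization and batch sampling.
#' @param optimizer_id registered optimizer (default `"adam"`).
#' @param optimizer_params hyperparameters; defaults: `lr = 2.5e-3`,
#'   `lr_min = 1e-4` (cosine decay over `steps`), adam moments (0.9, 0.999).
#' @param guidance optional [guidance_config()].
#' @param depth weight layers of the network (default 7).
#' @param bytes_per_param 4 (float32) or 2 (float16) weight storage.
#' @param log_every trace/report interval in steps.
#' @param verbose print structured per-interval log lines.
#' @return a `nif_config` list.
#' @export
compression_config <- function(target_cr, steps = 5000L, batch_points = 65536L,
                               seed = 0L, optimizer_id = "adam",
                               optimizer_params = list(), guidance = NULL,
                               depth = 7L, bytes_per_param = 4L,
                               log_every = 100L, verbose = FALSE) {
  if (!is_count(steps)) nif_stop("steps must be >= 1", "nif_error_range")
  if (!is_count(batch_points)) nif_stop("batch_points must be >= 1", "nif_error_range")
  structure(list(
    target_cr = target_cr, steps = as.integer(steps),
    batch_points = as.integer(batch_points), seed = as.integer(seed),
    optimizer_id = optimizer_id, optimizer_params = optimizer_params,
    guidance = guidance, depth = as.integer(depth),
    bytes_per_param = as.integer(bytes_per_param),
    log_every = as.integer(log_every), verbose = isTRUE(verbose)
  ), class = "nif_config")
}

cosine_lr <- function(step, steps, lr0, lr_min) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * step / steps))
}

# Core fitting engine shared by compress() and the hybrid residual fit.
# `values` are normalized pixel values in row-major grid order.
train_engine <- function(values, shape, width, cfg, guidance_ctx = NULL) {
  n <- length(values)
  batch <- min(cfg$batch_points, n)
  lr0 <- cfg$optimizer_params$lr %||% 2.5e-3
  lr_min <- cfg$optimizer_params$lr_min %||% 1e-4
  model <- init_model(length(shape), 1L, width, cfg$depth,
                      omega0 = cfg$optimizer_params$omega0 %||% 30,
                      seed = cfg$seed)
  # init refinement: start the output bias at the target mean so the first
  # epochs fit structure instead of the DC level
  model$b[[length(model$b)]][] <- mean(values)
  theta <- pack_params(model)
  opt <- optimizer_init(cfg$optimizer_id, length(theta), cfg$optimizer_params)
  trace <- data.frame(step = integer(0), loss = numeric(0))
  t0 <- proc.time()[["elapsed"]]
  with_seed(cfg$seed, {
    perm <- sample.int(n)
    ptr <- 1L
    for (step in seq_len(cfg$steps)) {
      if (ptr + batch - 1L > n) { perm <- sample.int(n); ptr <- 1L }
      take <- perm[ptr:(ptr + batch - 1L)]
      ptr <- ptr + batch
      coords <- coords_for_indices(shape, flat_to_multi(take - 1, shape))
      cache <- model_forward(model, coords, fast = TRUE, cache = TRUE)
      resid <- cache$out[, 1L] - values[take]
      loss <- mean(resid^2)
      dout <- matrix(2 * resid / length(resid), ncol = 1L)
      g <- pack_grads(model, model_backward(model, cache, dout))
      if (!is.null(guidance_ctx)) {
        gres <- guidance_ctx$grad_fn(model, step)
        if (!is.null(gres)) {
          g <- g + guidance_ctx$weight * gres$grad
          loss <- loss + guidance_ctx$weight * gres$loss
        }
      }
      if (!is.finite(loss))
        nif_stop(sprintf("non-finite loss at step %d; aborting", step),
                 "nif_error_diverged")
      lr <- cosine_lr(step, cfg$steps, lr0, lr_min)
      upd <- optimizer_step(theta, g, opt, lr = lr)
      theta <- upd$params
      opt <- upd$state
      model <- unpack_params(model, theta)
      if (step %% cfg$log_every == 0L || step == cfg$steps || step == 1L) {
        trace <- rbind(trace, data.frame(step = step, loss = loss))
        if (cfg$verbose)
          cat(sprintf("step=%d loss=%.6g lr=%.3g elapsed=%.2fs\n",
                      step, loss, lr, proc.time()[["elapsed"]] - t0))
      }
    }
  })
  # store at the precision the payload will carry, so in-memory decoding
  # matches file-based decoding bit for bit
  rounder <- if (cfg$bytes_per_param == 2L) f16_round else f32_round
  model <- unpack_params(model, rounder(theta))
  list(model = model, trace = trace)
}

#' Compress an image into an .inif file
#'
#' Normalizes the image to the training range, sizes the network for
#' `cfg$target_cr`, fits it by seeded minibatch gradient descent on the
#' coordinate grid (plus any configured guidance loss), and serializes the
#' result. Identical image + config + seed produce byte-identical files.
#'
#' @param img a [nif_image].
#' @param cfg a [compression_config()].
#' @param path output path (default: tempfile with extension `.inif`).
#' @return an `inif_file` object: `path`, `plan`, `meta`, `model`, `trace`,
#'   `file_bytes`, `achieved_cr`.
#' @export
compress <- function(img, cfg, path = tempfile(fileext = ".inif")) {
  stopifnot(inherits(img, "nif_image"), inherits(cfg, "nif_config"))
  nm <- minmax_normalize(img)
  plan <- plan_architecture(img$shape, img$dtype_code, cfg$target_cr,
                            depth = cfg$depth,
                            bytes_per_param = cfg$bytes_per_param,
                            axes = img$axes)
  gctx <- build_guidance_context(cfg$guidance, nm$image, cfg)
  fit <- train_engine(flatten_rm(nm$image$data), img$shape,
                      plan$chosen_width, cfg, guidance_ctx = gctx)
  meta <- inif_metadata(
    axes = img$axes, shape = img$shape, dtype_code = img$dtype_code,
    norm = nm$params, depth = cfg$depth, width = plan$chosen_width,
    in_dim = plan$in_dim, out_dim = 1L,
    omega0 = cfg$optimizer_params$omega0 %||% 30,
    seed = cfg$seed, bytes_per_param = cfg$bytes_per_param,
    extra = guidance_meta(cfg$guidance))
  bytes <- write_inif(fit$model, meta, path)
  structure(list(
    path = path, plan = plan, meta = meta, model = fit$model,
    trace = fit$trace, file_bytes = bytes,
    achieved_cr = compression_ratio(plan$raw_bytes, bytes)
  ), class = "inif_file")
}

#' @export
print.inif_file <- function(x, ...) {
  cat(sprintf("<inif_file> %s: %d bytes, achieved CR %.2f (target %g)\n",
              x$path, x$file_bytes, x$achieved_cr, x$plan$target_cr))
  invisible(x)
}

#' Evaluate a compressed file against its source image
#'
#' @param img the original [nif_image].
#' @param file an `inif_file` object or path to an `.inif` file.
#' @return list with `psnr` (dB, `Inf` when identical), `ssim`, and
#'   `achieved_cr`.
#' @export
evaluate <- function(img, file) {
  dec <- decode(file)
  if (!identical(dim(dec$data), dim(img$data)))
    nif_stop("shape mismatch between image and file", "nif_error_shape")
  fb <- if (inherits(file, "inif_file")) file$file_bytes else file.size(file)
  list(
    psnr = psnr(img, dec),
    ssim = ssim(img, dec),
    achieved_cr = compression_ratio(raw_pixel_bytes(img$shape, img$dtype_code), fb)
  )
}
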