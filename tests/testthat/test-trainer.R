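test_that("mse_loss matches a naive two-pass summation", {
  expect_equal(mse_loss(1:5, 1:5), 0)
  expect_equal(mse_loss(c(0, 0), c(3, 4)), 12.5)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(101); b <- rnorm(101)
    acc <- 0
    for (j in seq_along(a)) acc <- acc + (a[j] - b[j])^2
    expect_equal(mse_loss(a, b), acc / 101, tolerance = 1e-12)
  }
  expect_error(mse_loss(numeric(0), numeric(0)), class = "nif_error_empty")
})

test_that("optimizer registry implements sgd and adam correctly", {
  st <- optimizer_init("sgd", 3, list(lr = 0.5))
  r <- optimizer_step(c(1, 2, 3), c(0, 0, 0), st)
  expect_equal(r$params, c(1, 2, 3))          # zero gradient is a fixed point
  expect_equal(r$state$step_index, 1L)
  # two sgd steps on f(p) = p^2 from p = 1 with lr = 0.5: 1 -> 0 -> 0
  p <- 1
  st <- optimizer_init("sgd", 1, list(lr = 0.5))
  for (k in 1:2) {
    r <- optimizer_step(p, 2 * p, st)
    p <- r$params; st <- r$state
  }
  expect_equal(p, 0)
  # one adam step, hand-executed with bias correction:
  # m_hat = g, v_hat = g^2  =>  p' = -lr * g/(|g| + eps) ~ -0.1
  st <- optimizer_init("adam", 1, list(lr = 0.1))
  r <- optimizer_step(0, 1, st)
  expect_equal(r$params, -0.1 * 1 / (1 + 1e-8), tolerance = 1e-12)
  expect_error(optimizer_init("no-such-optimizer", 1),
               class = "nif_error_optimizer")
  expect_error(optimizer_step(1, c(1, 2), st), class = "nif_error_shape")
})

test_that("custom optimizers can be registered through the hook", {
  register_optimizer("halving",
    init = function(n, opts) list(),
    step = function(params, grads, state, lr) {
      list(params = params - 0.5 * sign(grads), state = state)
    })
  st <- optimizer_init("halving", 2)
  r <- optimizer_step(c(1, -1), c(3, -3), st)
  expect_equal(r$params, c(0.5, -0.5))
})

test_that("a constant image is reproduced almost exactly", {
  img <- nif_image(array(1234L, c(16L, 16L, 16L)), c("Z", "Y", "X"), "u16")
  cfg <- compression_config(target_cr = 4, steps = 200, batch_points = 2048,
                            seed = 2, log_every = 100)
  fit <- compress(img, cfg)
  dec <- decode(fit)
  expect_gt(psnr(img, dec), 50)
})

test_that("compression is byte-deterministic given image, config and seed", {
  img <- make_nuclei_volume(c(10L, 14L, 14L), 1, 0.2, seed = 5)
  cfg <- compression_config(target_cr = 6, steps = 120, batch_points = 1024,
                            seed = 3, log_every = 60)
  f1 <- compress(img, cfg, withr::local_tempfile(fileext = ".inif"))
  f2 <- compress(img, cfg, withr::local_tempfile(fileext = ".inif"))
  expect_identical(readBin(f1$path, raw(), file.size(f1$path)),
                   readBin(f2$path, raw(), file.size(f2$path)))
})

test_that("training reduces the loss below its initial value", {
  img <- make_nuclei_volume(c(16L, 32L, 32L), 3, 0.25, seed = 12)
  cfg <- compression_config(target_cr = 4, steps = 400, batch_points = 8192,
                            seed = 1, log_every = 100)
  fit <- compress(img, cfg)
  expect_lt(tail(fit$trace$loss, 1), head(fit$trace$loss, 1))
  ev <- evaluate(img, fit)
  expect_gte(ev$achieved_cr, 4)
  expect_true(is.finite(ev$psnr) || ev$psnr == Inf)
})

test_that("a depth-2 model converges to the least-squares affine fit", {
  # linear model + full-grid batches: gradient descent on a quadratic must
  # approach the closed-form regression of values on coordinates
  set.seed(6)
  img <- nif_image(array(as.integer(
    round(runif(256, 200, 64000))), c(16L, 16L)), c("Y", "X"), "u16")
  nm <- minmax_normalize(img)
  grid <- make_grid(img$shape)
  y <- inif:::flatten_rm(nm$image$data)
  ls <- lm.fit(cbind(1, grid$coords), y)$coefficients
  cfg <- compression_config(target_cr = 1.01, steps = 4000, batch_points = 256,
                            seed = 1, depth = 2L,
                            optimizer_params = list(lr = 5e-2, lr_min = 1e-3),
                            log_every = 1000)
  fit <- compress(img, cfg)
  w <- as.vector(fit$model$W[[1]])
  b <- fit$model$b[[1]]
  expect_equal(unname(c(b, w)), unname(c(ls[1], ls[2], ls[3])),
               tolerance = 0.02)
})

test_that("reconstruction quality is non-decreasing in model width", {
  img <- make_filament_image(c(24L, 24L), 2, 6, seed = 9)
  med_psnr <- vapply(c(4L, 10L, 20L), function(w) {
    ps <- vapply(1:5, function(seed) {
      nm <- minmax_normalize(img)
      fit <- inif:::train_engine(inif:::flatten_rm(nm$image$data), img$shape, w,
        compression_config(target_cr = 2, steps = 300, batch_points = 576,
                           seed = seed, log_every = 300))
      meta <- inif:::inif_metadata(img$axes, img$shape, "u16", nm$params,
                                   7, w, 2, 1, 30, seed, 4L)
      dec <- decode(list(model = fit$model, meta = meta))
      psnr(img, dec)
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_psnr) >= 0))
})

test_that("non-finite losses abort with a diagnostic", {
  # an absurd learning rate drives the linear head past double range in a
  # couple of steps; the trainer must stop, not restart silently
  img <- make_nuclei_volume(c(16L, 16L, 16L), 1, 0.2, seed = 5)
  cfg <- compression_config(target_cr = 4, steps = 50, batch_points = 512,
                            seed = 1, optimizer_params = list(lr = 1e200))
  expect_error(suppressWarnings(compress(img, cfg)),
               class = "nif_error_diverged")
})
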