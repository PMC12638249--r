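test_that("iou handles identity, disjoint, partial and empty masks", {
  a <- c(1, 1, 0, 0)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(c(1, 0), c(0, 1)), 0)
  expect_equal(iou(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1 / 3)
  expect_equal(iou(numeric(4), numeric(4)), 1)
  expect_error(iou(1:3, 1:4), class = "nif_error_shape")
  # symmetry and range; soft == hard on binary inputs
  set.seed(4)
  for (i in 1:10) {
    x <- round(runif(30)); y <- round(runif(30))
    expect_equal(iou(x, y), iou(y, x))
    expect_gte(iou(x, y), 0); expect_lte(iou(x, y), 1)
    inter <- sum(x & y); uni <- sum(x | y)
    expect_equal(iou(x, y), if (uni == 0) 1 else inter / uni)
  }
})

test_that("the reference segmenter finds lines and drops specks", {
  blank <- matrix(0, 64, 64)
  expect_equal(sum(reference_segment(blank)), 0)
  line <- matrix(0, 64, 64)
  line[32, 7:57] <- 30000
  m <- reference_segment(line)
  expect_true(all(m[32, 7:57]))
  # every surviving component is at least min_object_size pixels
  lab <- inif:::.label_components(m, dim(m))
  expect_true(all(tabulate(lab) >= 20))
  speck <- matrix(0, 64, 64)
  speck[20, 20:24] <- 30000
  expect_equal(sum(reference_segment(speck)), 0)
  expect_error(reference_segment(array(0, c(2, 2, 2, 2))),
               class = "nif_error_shape")
})

test_that("the soft mask converges to the hard threshold as temp -> 0", {
  img <- make_filament_image(c(48L, 48L), 3, 8, seed = 2)
  x01 <- minmax_normalize(img)$image$data / 100
  p <- seg_params(soft_threshold_temp = 1e-6)
  s <- soft_segment(x01, p, contrast = c(0, 1))
  sm <- inif:::smooth_gauss(x01, 1)
  r <- inif:::ridge_response(sm, 1)
  hard <- r > 0.01
  away <- abs(r - 0.01) > 1e-3
  expect_lt(max(abs(s[away] - hard[away])), 0.01)
  expect_error(soft_segment(x01, seg_params(soft_threshold_temp = 0)),
               class = "nif_error_range")
})

test_that("segmentation loss gradient passes the finite-difference check", {
  set.seed(5)
  p <- seg_params(soft_threshold_temp = 0.05)
  x <- matrix(runif(16 * 16), 16, 16)
  o <- matrix(runif(16 * 16), 16, 16)
  sl <- inif:::segmentation_loss_grad(x, o, p)
  h <- 1e-5
  idx <- sample(256, 40)
  gn <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (segmentation_loss(xp, o, p) - segmentation_loss(xm, o, p)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(sl$grad[idx] - gn)) / max(abs(gn)), 1e-3)
})

test_that("segmentation loss is zero-ish at identity and ~1 when structure is lost", {
  # exactness at identity and on disjoint masks is a cold-temperature
  # (near-binary) property; the warm training default trades it for
  # usable gradients
  img <- make_filament_image(c(96L, 96L), 5, 8, seed = 2)
  nm <- minmax_normalize(img)$image$data / 100
  p <- seg_params(soft_threshold_temp = 1e-4)
  expect_lt(segmentation_loss(nm, nm, p), 0.01)
  expect_gt(segmentation_loss(matrix(0.1, 96, 96), nm, p), 0.99)
})

test_that("segmentation loss falls as decoded blends toward the original", {
  img <- make_filament_image(c(96L, 96L), 5, 8, seed = 2)
  nm <- minmax_normalize(img)$image$data / 100
  set.seed(3)
  noise <- matrix(runif(96 * 96), 96, 96)
  for (p in list(seg_params(), seg_params(soft_threshold_temp = 0.005))) {
    losses <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(al)
      segmentation_loss(al * nm + (1 - al) * noise, nm, p), numeric(1))
    expect_true(all(diff(losses) < 0))
  }
})

test_that("perceptual loss is zero at identity and MSE for identity features", {
  set.seed(6)
  ph <- matrix(runif(64), 8, 8)
  pr <- matrix(runif(64), 8, 8)
  net <- feature_net(seed = 1)
  expect_equal(perceptual_loss(ph, ph, net), 0)
  expect_equal(perceptual_loss(ph, pr, identity_feature_net()),
               mean((ph - pr)^2))
  expect_error(perceptual_loss(ph, pr, net, w = list(1)),
               class = "nif_error_shape")
})

test_that("perceptual loss equals a naive per-pixel loop implementation", {
  set.seed(7)
  net <- feature_net(seed = 1, channels = c(4L, 4L))
  ph <- matrix(runif(64), 8, 8)
  pr <- matrix(runif(64), 8, 8)
  naive_conv <- function(x, w) {
    k <- dim(w)[1]; r <- (k - 1) / 2
    H <- dim(x)[1]; W <- dim(x)[2]
    out <- array(0, c(H, W, dim(w)[4]))
    for (co in seq_len(dim(w)[4])) for (y in 1:H) for (xx in 1:W) {
      s <- 0
      for (u in -r:r) for (v in -r:r) for (ci in seq_len(dim(w)[3])) {
        yy <- y + u; xx2 <- xx + v
        if (yy >= 1 && yy <= H && xx2 >= 1 && xx2 <= W)
          s <- s + x[yy, xx2, ci] * w[u + r + 1, v + r + 1, ci, co]
      }
      out[y, xx, co] <- s
    }
    out
  }
  feats <- function(x) {
    h <- array(x, c(8, 8, 1))
    out <- list()
    for (i in seq_along(net$weights)) {
      h <- pmax(naive_conv(h, net$weights[[i]]), 0)
      out[[i]] <- h
    }
    out
  }
  fh <- feats(ph); fr <- feats(pr)
  ref <- sum(vapply(seq_along(fh), function(i)
    sum((fh[[i]] - fr[[i]])^2) / 64, numeric(1)))
  expect_lt(abs(perceptual_loss(ph, pr, net) - ref), 1e-10)
})

test_that("patch sampling is seeded, uniform, and covers the full-size case", {
  prov <- function(y0, x0, s) matrix(0, s, s)
  ref <- matrix(runif(64 * 64), 64, 64)
  p <- perc_params(patch_size = 16L)
  r1 <- sample_guided_patches(prov, ref, p, seed = 9)
  r2 <- sample_guided_patches(prov, ref, p, seed = 9)
  expect_identical(r1$loc_hat, r2$loc_hat)
  expect_identical(r1$loc_ref, r2$loc_ref)
  # full-size patch has a single possible location
  rf <- sample_guided_patches(prov, ref, perc_params(patch_size = 64L), seed = 1)
  expect_equal(rf$loc_ref, c(0L, 0L))
  expect_identical(rf$patch_ref, ref)
  expect_error(sample_guided_patches(prov, ref, perc_params(65L), 1),
               class = "nif_error_shape")
  # 10,000 draws on a 64x64 source with 16x16 patches: uniform over 49x49
  locs <- t(vapply(1:10000, function(s)
    sample_guided_patches(prov, ref, p, seed = s)$loc_ref, integer(2)))
  counts <- table(factor(locs[, 1], levels = 0:48))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  counts2 <- table(factor(locs[, 2], levels = 0:48))
  expect_gt(stats::chisq.test(as.vector(counts2))$p.value, 0.01)
})

test_that("zero guidance weight reproduces the unguided trainer bit-exactly", {
  img <- make_filament_image(c(32L, 32L), 2, 6, seed = 3)
  base <- compression_config(target_cr = 2, steps = 80, batch_points = 1024,
                             seed = 5, log_every = 40)
  guided0 <- compression_config(target_cr = 2, steps = 80, batch_points = 1024,
                                seed = 5, log_every = 40,
                                guidance = guidance_config("segmentation",
                                                           weight = 0))
  f1 <- compress(img, base, withr::local_tempfile(fileext = ".inif"))
  f2 <- compress(img, guided0, withr::local_tempfile(fileext = ".inif"))
  expect_identical(readBin(f1$path, raw(), file.size(f1$path)),
                   readBin(f2$path, raw(), file.size(f2$path)))
})

test_that("guided training with either mode runs and logs a finite loss", {
  img <- make_filament_image(c(32L, 32L), 2, 5, seed = 4)
  gseg <- compression_config(target_cr = 2, steps = 30, batch_points = 1024,
    seed = 1, guidance = guidance_config("segmentation", weight = 0.2),
    log_every = 10)
  fseg <- compress(img, gseg)
  expect_true(all(is.finite(fseg$trace$loss)))
  ref <- make_filament_image(c(32L, 32L), 2, 5, seed = 44)
  gperc <- compression_config(target_cr = 2, steps = 30, batch_points = 1024,
    seed = 1, guidance = guidance_config("perceptual", weight = 0.2,
      perc_params = perc_params(patch_size = 8L), reference = ref),
    log_every = 10)
  fperc <- compress(img, gperc)
  expect_true(all(is.finite(fperc$trace$loss)))
  expect_equal(fperc$meta$guidance$mode, "perceptual")
})
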