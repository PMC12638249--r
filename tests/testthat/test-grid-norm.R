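test_that("min-max normalization maps to the requested range", {
  img <- nif_image(array(c(0, 50, 200), 3L), "X", "u16")
  nm <- minmax_normalize(img, 0, 100)
  expect_equal(as.vector(nm$image$data), c(0, 25, 100))
  expect_equal(nm$params$src_min, 0)
  expect_equal(nm$params$src_max, 200)

  set.seed(7)
  rnd <- tiny_u16(c(5L, 9L), seed = 7)
  nm2 <- minmax_normalize(rnd)
  expect_equal(min(nm2$image$data), 0)
  expect_equal(max(nm2$image$data), 100)
})

test_that("constant images normalize to lo without division by zero", {
  img <- nif_image(array(42L, c(3L, 3L)), c("Y", "X"), "u16")
  nm <- minmax_normalize(img)
  expect_true(all(nm$image$data == 0))
  back <- denormalize(nm$image, nm$params, "u16")
  expect_identical(back$data, img$data)
})

test_that("normalization rejects empty and non-finite input", {
  expect_error(minmax_normalize(nif_image(array(c(1, NaN), 2L), "X", "f32")),
               class = "nif_error_nonfinite")
  expect_error(minmax_normalize(numeric(0)), class = "nif_error_empty")
  expect_error(minmax_normalize(tiny_u16(), lo = 5, hi = 5),
               class = "nif_error_range")
})

test_that("normalize/denormalize round-trips u8 and u16 images exactly", {
  for (dt in c("u8", "u16")) {
    for (seed in 1:5) {
      set.seed(seed)
      mx <- if (dt == "u8") 255L else 65535L
      v <- sample.int(mx + 1L, 60, replace = TRUE) - 1L
      img <- nif_image(array(as.integer(v), c(3L, 4L, 5L)),
                       c("Z", "Y", "X"), dt)
      nm <- minmax_normalize(img)
      back <- denormalize(nm$image, nm$params, dt)
      expect_identical(back$data, img$data)
    }
  }
})

test_that("denormalization clips to the dtype range", {
  params <- inif:::normalization_params(0, 255, 0, 100)
  out <- denormalize(array(150, 1L), params, "u8")
  expect_equal(as.vector(out$data), 255L)
  expect_equal(as.vector(denormalize(array(100, 1L),
    inif:::normalization_params(0, 200, 0, 100), "f32")$data), 200)
  expect_error(denormalize(array(1, 1L), params, "u64"),
               class = "nif_error_dtype")
})

test_that("coordinate grids span [-1, 1] with the stated endpoint formula", {
  expect_equal(make_grid(3L)$coords[, 1], c(-1, 0, 1))
  g <- make_grid(c(2L, 2L))
  expect_equal(g$coords, rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  g15 <- make_grid(c(1L, 5L))
  expect_true(all(g15$coords[, 1] == 0))
  expect_equal(nrow(g15$coords), 5L)
  set.seed(1)
  for (i in 1:5) {
    shp <- sample(1:7, sample(1:5, 1), replace = TRUE)
    co <- make_grid(shp)$coords
    expect_true(all(co >= -1 & co <= 1))
    expect_equal(nrow(co), prod(shp))
  }
  expect_error(make_grid(c(3L, 0L)), class = "nif_error_shape")
})

test_that("grid construction is a pure function", {
  expect_identical(make_grid(c(4L, 5L, 6L)), make_grid(c(4L, 5L, 6L)))
})

test_that("coords_for_indices agrees exactly with full-grid rows", {
  set.seed(42)
  for (i in 1:8) {
    shp <- sample(1:9, sample(1:4, 1), replace = TRUE)
    full <- make_grid(shp)$coords
    n <- prod(shp)
    take <- sample(n, min(n, 25))
    idx <- inif:::flat_to_multi(take - 1, shp)
    expect_identical(coords_for_indices(shp, idx),
                     full[take, , drop = FALSE])
  }
  # whole grid in order reproduces make_grid output
  shp <- c(3L, 4L)
  idx <- inif:::flat_to_multi(0:11, shp)
  expect_identical(coords_for_indices(shp, idx), make_grid(shp)$coords)
  # single first index equals the first row
  expect_identical(coords_for_indices(shp, matrix(c(0, 0), 1)),
                   make_grid(shp)$coords[1, , drop = FALSE])
  expect_error(coords_for_indices(shp, matrix(c(3, 0), 1)),
               class = "nif_error_bounds")
})

test_that("a Z-slice of the worked-example volume has 624*924 coordinates", {
  shp <- c(65L, 624L, 924L)
  idx <- inif:::subgrid_indices(list(32L, 0:623, 0:923))
  co <- coords_for_indices(shp, idx)
  expect_equal(nrow(co), 624L * 924L)
  expect_true(all(co[, 1] == co[1, 1]))
})

test_that("axes are canonicalized and validated", {
  arr <- array(1:24, c(4L, 3L, 2L))
  img <- nif_image(arr, c("X", "Y", "Z"))   # given out of order
  expect_equal(img$axes, c("Z", "Y", "X"))
  expect_equal(img$shape, c(2L, 3L, 4L))
  expect_equal(img$data[1, 2, 3], arr[3, 2, 1])
  expect_error(nif_image(arr, c("Z", "Z", "X")), class = "nif_error_axes")
  expect_error(nif_image(arr, c("A", "Y", "X")), class = "nif_error_axes")
})
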