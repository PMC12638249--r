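make_test_meta <- function(model, shape = c(8L, 8L), dtype = "u16",
                           bpp = 4L, seed = 1L) {
  inif:::inif_metadata(tail(c("Z", "Y", "X"), length(shape)), shape, dtype,
                       inif:::normalization_params(12, 50123), model$depth,
                       model$width, model$in_dim, model$out_dim, 30, seed, bpp)
}

test_that("write/read round-trips weights and metadata bit-exactly", {
  m <- init_model(2, 1, 6, 5, 30, seed = 11)
  tf <- withr::local_tempfile(fileext = ".inif")
  n <- write_inif(m, make_test_meta(m), tf)
  expect_equal(n, file.size(tf))
  f <- read_inif(tf)
  expect_identical(inif:::pack_params(f$model),
                   inif:::f32_round(inif:::pack_params(m)))
  expect_equal(f$meta$payload_len, parameter_count(m) * 4L)
  expect_equal(as.integer(f$meta$shape), c(8L, 8L))
  expect_equal(f$meta$norm$src_max, 50123)
  # forward outputs are identical to the float32-stored master
  m32 <- inif:::unpack_params(m, inif:::f32_round(inif:::pack_params(m)))
  co <- matrix(runif(20, -1, 1), 10, 2)
  expect_identical(forward(f$model, co), forward(m32, co))
})

test_that("decoding from file equals decoding from memory on random models", {
  set.seed(21)
  for (i in 1:10) {
    w <- sample(2:10, 1); d <- sample(c(2L, 4L, 7L), 1)
    m <- init_model(3, 1, w, d, 30, seed = i)
    theta <- inif:::pack_params(m) * runif(parameter_count(m), -2, 2)
    m <- inif:::unpack_params(m, inif:::f32_round(theta))
    meta <- make_test_meta(m, c(4L, 5L, 6L))
    tf <- withr::local_tempfile(fileext = ".inif")
    write_inif(m, meta, tf)
    mem <- decode(list(model = m, meta = meta))
    disk <- decode(tf)
    expect_identical(mem$data, disk$data)
  }
})

test_that("payload corruption, truncation, bad magic and bad version are told apart", {
  m <- init_model(2, 1, 5, 4, 30, seed = 2)
  tf <- withr::local_tempfile(fileext = ".inif")
  write_inif(m, make_test_meta(m), tf)
  b <- readBin(tf, raw(), file.size(tf))

  flip <- b
  flip[length(b) - 5L] <- as.raw(bitwXor(as.integer(flip[length(b) - 5L]), 255L))
  t1 <- withr::local_tempfile(); writeBin(flip, t1)
  expect_error(read_inif(t1), class = "nif_error_checksum")

  t2 <- withr::local_tempfile(); writeBin(b[1:(length(b) - 9L)], t2)
  expect_error(read_inif(t2), "truncated payload", class = "nif_error_truncated")

  bad <- b; bad[3] <- as.raw(0x00)
  t3 <- withr::local_tempfile(); writeBin(bad, t3)
  expect_error(read_inif(t3), class = "nif_error_magic")

  # bump format_version inside the JSON header
  hl <- readBin(b[5:8], "integer", size = 4L, endian = "little")
  hdr <- rawToChar(b[9:(8L + hl)])
  hdr2 <- sub("\"format_version\":1", "\"format_version\":9", hdr, fixed = TRUE)
  b4 <- c(b[1:4], writeBin(nchar(hdr2), raw(), size = 4L, endian = "little"),
          charToRaw(hdr2), b[(9L + hl):length(b)])
  t4 <- withr::local_tempfile(); writeBin(b4, t4)
  expect_error(read_inif(t4), class = "nif_error_version")
})

test_that("float16 payloads decode with only cast error", {
  m <- init_model(2, 1, 8, 5, 30, seed = 3)
  tf <- withr::local_tempfile(fileext = ".inif")
  write_inif(m, make_test_meta(m, bpp = 2L), tf)
  f <- read_inif(tf)
  expect_equal(f$meta$payload_len, parameter_count(m) * 2L)
  theta <- inif:::pack_params(m)
  expect_identical(inif:::pack_params(f$model), inif:::f16_round(theta))
  # cast error bound for half precision on these magnitudes
  expect_lt(max(abs(inif:::pack_params(f$model) - theta)), 2^-10 * 32)
})

test_that("float16 conversion round-trips representable values", {
  vals <- c(0, 1, -1, 0.5, 30, -30, 1024, 2^-14, 65504)
  expect_equal(inif:::f16_round(vals), vals)
  # round-to-nearest-even on halfway cases
  expect_equal(inif:::f16_round(2049 / 2048), 1)        # rounds down to even
  set.seed(4)
  x <- runif(200, -5, 5)
  expect_lt(max(abs(inif:::f16_round(x) - x) / pmax(abs(x), 1e-6)), 2^-10)
})

test_that("crc32 matches known vectors", {
  # standard test vector: "123456789" -> 0xCBF43926
  expect_identical(inif:::crc32_hex(charToRaw("123456789")), "cbf43926")
  expect_identical(inif:::crc32_hex(raw(0)), "00000000")
})
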