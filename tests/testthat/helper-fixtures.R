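# Shared fixtures and independent oracles, all generated in code.

tiny_u16 <- function(shape = c(6L, 8L), seed = 1L) {
  set.seed(seed)
  v <- sample.int(60000L, prod(shape), replace = TRUE)
  nif_image(array(as.integer(v), shape),
            tail(c("T", "C", "Z", "Y", "X"), length(shape)), "u16")
}

# A quickly trained small model for decoder tests (cached per session).
trained_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      img <- make_nuclei_volume(c(12L, 20L, 20L), 2, 0.2, seed = 31)
      cfg <- compression_config(target_cr = 6, steps = 150,
                                batch_points = 2048, seed = 4, log_every = 50)
      cache <<- list(img = img, fit = compress(img, cfg))
    }
    cache
  }
})

# Naive O(n * params) central-difference gradient for small models; the
# independent oracle for the analytic backward pass.
fd_gradient <- function(model, coords, y, h = 1e-4) {
  theta <- inif:::pack_params(model)
  lossf <- function(th) {
    mm <- inif:::unpack_params(model, th)
    p <- inif:::model_forward(mm, coords, fast = TRUE)
    mean((p[, 1] - y)^2)
  }
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (lossf(tp) - lossf(tm)) / (2 * h)
  }, numeric(1))
}

analytic_gradient <- function(model, coords, y) {
  cache <- inif:::model_forward(model, coords, fast = TRUE, cache = TRUE)
  dout <- matrix(2 * (cache$out[, 1] - y) / length(y), ncol = 1)
  inif:::pack_grads(model, inif:::model_backward(model, cache, dout))
}

# Brute-force parameter count: enumerate every stored tensor.
count_by_enumeration <- function(model) {
  n <- sum(vapply(model$W, length, numeric(1))) +
       sum(vapply(model$b, length, numeric(1))) +
       length(model$omega)
  as.integer(n)
}
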