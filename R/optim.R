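# Pluggable optimizer registry. Built-ins: adam (default) and sgd. Learned
# optimizers can be registered through the same step signature.

.optimizers <- new.env(parent = emptyenv())

#' Register an optimizer
#'
#' @param id string identifier.
#' @param init `function(n_params, opts)` returning the initial state (a list;
#'   `step_index` is managed by the framework).
#' @param step `function(params, grads, state, lr)` returning
#'   `list(params = ..., state = ...)`; `lr` may be `NULL` to use the state's
#'   own learning rate.
#' @return invisibly, `id`.
#' @export
register_optimizer <- function(id, init, step) {
  assign(id, list(init = init, step = step), envir = .optimizers)
  invisible(id)
}

#' Create optimizer state
#'
#' @param id registered optimizer id (`"adam"`, `"sgd"`, or user-registered).
#' @param n_params number of scalars being optimized.
#' @param opts named list of hyperparameters (e.g. `lr`, `beta1`, `beta2`).
#' @return an opaque state list with `step_index = 0`.
#' @export
optimizer_init <- function(id, n_params, opts = list()) {
  if (!exists(id, envir = .optimizers, inherits = FALSE))
    nif_stop(sprintf("unknown optimizer_id '%s'", id), "nif_error_optimizer")
  reg <- get(id, envir = .optimizers)
  st <- reg$init(n_params, opts)
  st$id <- id
  st$step_index <- 0L
  st
}

#' Apply one optimizer update
#'
#' Deterministic given `(params, grads, state)`. The step index advances by
#' exactly one per call.
#'
#' @param params numeric parameter vector.
#' @param grads gradient vector, same length.
#' @param state state from [optimizer_init()] or a previous step.
#' @param lr optional learning-rate override for this step (used by schedules).
#' @return `list(params, state)`.
#' @export
optimizer_step <- function(params, grads, state, lr = NULL) {
  if (length(grads) != length(params))
    nif_stop("gradient length does not match parameters", "nif_error_shape")
  reg <- get(state$id, envir = .optimizers)
  state$step_index <- state$step_index + 1L
  reg$step(params, grads, state, lr)
}

register_optimizer("sgd",
  init = function(n_params, opts) {
    list(lr = opts$lr %||% 1e-3)
  },
  step = function(params, grads, state, lr) {
    eta <- lr %||% state$lr
    list(params = params - eta * grads, state = state)
  })

register_optimizer("adam",
  init = function(n_params, opts) {
    list(lr = opts$lr %||% 1e-3,
         beta1 = opts$beta1 %||% 0.9,
         beta2 = opts$beta2 %||% 0.999,
         eps = opts$eps %||% 1e-8,
         m = numeric(n_params), v = numeric(n_params))
  },
  step = function(params, grads, state, lr) {
    eta <- lr %||% state$lr
    t <- state$step_index
    state$m <- state$beta1 * state$m + (1 - state$beta1) * grads
    state$v <- state$beta2 * state$v + (1 - state$beta2) * grads^2
    mhat <- state$m / (1 - state$beta1^t)
    vhat <- state$v / (1 - state$beta2^t)
    list(params = params - eta * mhat / (sqrt(vhat) + state$eps),
         state = state)
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
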