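#' Build the weight-transformation network
#'
#' The generator maps a length-`n` concatenated Dirichlet weight vector
#' through two ReLU hidden layers (width `hidden`, dropout after each)
#' into two linear heads of sizes `n1` and `n0`, each passed through its
#' own softmax, so every output is a pair of valid simplex vectors.
#' Parameters are drawn with the uniform fan-in scheme from R's current
#' RNG stream; covariates enter the model only through the training
#' losses, not as network inputs.
#'
#' @param n1,n0 Arm sizes (each at least 2).
#' @param hidden Width of both hidden layers.
#' @param dropout Dropout rate applied after each hidden layer; active
#'   during initialization, training and (by default) generation.
#' @param lr Adam learning rate for the network parameters.
#' @param lr_gamma Adam learning rate for the log kernel bandwidth.
#' @return An object of class `qrer_generator`.
#' @export
build_generator <- function(n1, n0, hidden = 512, dropout = 0.5,
                            lr = 1e-3, lr_gamma = 1e-3) {
  if (n1 < 2 || n0 < 2) abort("`n1` and `n0` must be at least 2")
  n <- n1 + n0
  fan_unif <- function(nr, nc) {
    lim <- 1 / sqrt(nr)
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list(
    A1 = fan_unif(n, hidden),      b1 = runif(hidden, -1 / sqrt(n), 1 / sqrt(n)),
    A2 = fan_unif(hidden, hidden), b2 = runif(hidden, -1 / sqrt(hidden), 1 / sqrt(hidden)),
    C1 = fan_unif(hidden, n1),     c1 = runif(n1, -1 / sqrt(hidden), 1 / sqrt(hidden)),
    C0 = fan_unif(hidden, n0),     c0 = runif(n0, -1 / sqrt(hidden), 1 / sqrt(hidden))
  )
  env <- new.env(parent = emptyenv())
  env$ptr <- net_create(n1, n0, params, lr, lr_gamma, 0)
  structure(
    list(
      env = env,
      n1 = n1, n0 = n0, n = n, hidden = hidden, dropout = dropout,
      lr = lr, lr_gamma = lr_gamma,
      params = params, log_gamma = 0,
      train_state = list(trained = FALSE)
    ),
    class = "qrer_generator"
  )
}

# live network handle; rebuilt from the stored parameter snapshot after
# deserialization (external pointers do not survive saveRDS)
generator_ptr <- function(model) {
  p <- model$env$ptr
  if (is.null(p)) {
    p <- net_create(model$n1, model$n0, model$params,
                    model$lr, model$lr_gamma, model$log_gamma)
    model$env$ptr <- p
  }
  p
}

# snapshot the live network state back into the (value-semantics) model
snapshot_generator <- function(model) {
  ptr <- generator_ptr(model)
  model$params <- net_get_params(ptr)
  model$log_gamma <- net_get_log_gamma(ptr)
  model
}

# fresh inverted-dropout masks from R's RNG (0 or 1/keep)
dropout_masks <- function(nr, nc, rate) {
  keep <- 1 - rate
  list(
    M1 = matrix((runif(nr * nc) < keep) / keep, nr, nc),
    M2 = matrix((runif(nr * nc) < keep) / keep, nr, nc)
  )
}

#' Forward pass of the generator
#'
#' Transforms raw weight vectors (rows) into generated weight vectors.
#' With `dropout_active = TRUE` fresh dropout masks are drawn from R's
#' RNG; otherwise the pass is deterministic given the parameters.
#'
#' @param model A `qrer_generator`.
#' @param weights Matrix of input weight vectors (rows), canonical order.
#' @param dropout_active Draw and apply dropout masks?
#' @return Matrix of transformed weight vectors, same shape.
#' @export
forward_generator <- function(model, weights, dropout_active = FALSE) {
  stopifnot(inherits(model, "qrer_generator"))
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  ptr <- generator_ptr(model)
  out <- if (dropout_active) {
    m <- dropout_masks(nrow(weights), model$hidden, model$dropout)
    net_forward(ptr, weights, m$M1, m$M2)
  } else {
    net_forward(ptr, weights, NULL, NULL)
  }
  # exact double-precision renormalization of the two softmax blocks (the
  # single-precision forward pass sums to 1 only to ~1e-7)
  i1 <- seq_len(model$n1)
  i0 <- model$n1 + seq_len(model$n0)
  out[, i1] <- out[, i1, drop = FALSE] / rowSums(out[, i1, drop = FALSE])
  out[, i0] <- out[, i0, drop = FALSE] / rowSums(out[, i0, drop = FALSE])
  out
}

#' Identity-map initialization of the generator
#'
#' Pre-trains the network toward the identity on the weight simplices by
#' minimizing the mean squared error between the logarithms of the input
#' and output weights over a fixed batch of Dirichlet draws. Dropout is
#' active during these steps.
#'
#' @param model A `qrer_generator`.
#' @param init_weights Matrix of Dirichlet weight vectors (rows) used as
#'   the fixed pre-training batch.
#' @param n_steps Number of Adam steps.
#' @return The model, with the per-step initialization loss recorded in
#'   `train_state$init_loss`.
#' @export
initialize_identity <- function(model, init_weights, n_steps = 500) {
  stopifnot(inherits(model, "qrer_generator"))
  ptr <- generator_ptr(model)
  losses <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    m <- dropout_masks(nrow(init_weights), model$hidden, model$dropout)
    losses[s] <- net_init_step(ptr, init_weights, m$M1, m$M2)
    if (!is.finite(losses[s])) {
      abort(paste0("nonfinite initialization loss at step ", s))
    }
  }
  model <- snapshot_generator(model)
  model$train_state$init_loss <- losses
  model
}

#' Generate transformed weight vectors from a trained model
#'
#' Draws `m` fresh Dirichlet weight vectors and pushes them through the
#' generator. Dropout stays active by default, matching the training-time
#' forward pass: the generator learns to place the weighted mean
#' differences with dropout noise in the loop, and switching it off at
#' generation collapses the diversity of the outputs (the weighted
#' balance distribution then no longer matches rerandomization). Set
#' `dropout_active = FALSE` for a deterministic map of the Dirichlet
#' draw.
#'
#' @param model A `qrer_generator` (or [qrer] fit).
#' @param m Number of weight vectors.
#' @param dropout_active Apply dropout during generation?
#' @return An `m` by `n` matrix of weight vectors, canonical order.
#' @export
generate_weights <- function(model, m = 1000, dropout_active = TRUE) {
  if (inherits(model, "qrer_fit")) model <- model$model
  stopifnot(inherits(model, "qrer_generator"))
  W <- sample_dirichlet_weights(model$n1, model$n0, m)
  forward_generator(model, W, dropout_active = dropout_active)
}

#' @export
print.qrer_generator <- function(x, ...) {
  cat("<qrer_generator> input ", x$n, " -> ", x$hidden, " -> ", x$hidden,
      " -> (", x$n1, " | ", x$n0, ") double softmax\n", sep = "")
  if (isTRUE(x$train_state$trained)) {
    cat("  trained: ", x$train_state$iterations, " iterations, best KS metric ",
        signif(x$train_state$best_metric, 4), ", gamma ",
        signif(exp(x$log_gamma), 4), "\n", sep = "")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' Save / load a trained generator
#'
#' The checkpoint is an RDS of the parameter snapshot plus a JSON sidecar
#' with the architecture and training state.
#'
#' @param model A `qrer_generator`.
#' @param path Checkpoint path (`.rds`); the sidecar gets `.json`.
#' @return `qrer_save_model` returns `path` invisibly; `qrer_load_model`
#'   returns the restored model.
#' @export
qrer_save_model <- function(model, path) {
  stopifnot(inherits(model, "qrer_generator"))
  model <- snapshot_generator(model)
  obj <- model[setdiff(names(model), "env")]
  saveRDS(obj, path)
  side <- list(
    n1 = model$n1, n0 = model$n0, hidden = model$hidden,
    dropout = model$dropout, gamma = exp(model$log_gamma),
    train_state = model$train_state[setdiff(names(model$train_state),
                                            c("init_loss"))]
  )
  jsonlite::write_json(side, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname qrer_save_model
#' @export
qrer_load_model <- function(path) {
  obj <- readRDS(path)
  obj$env <- new.env(parent = emptyenv())
  class(obj) <- "qrer_generator"
  obj
}
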