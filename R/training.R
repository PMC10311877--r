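#' Training configuration
#'
#' Hyper-parameters of the quasi-rerandomization training loop. The
#' defaults are the study settings: batch size 512, pools of 1000 / 1000
#' / 10000 vectors for initialization, early stopping and loss
#' computation, 500 initialization steps, up to 5000 training iterations,
#' patience of 15 evaluations, and both regularization coefficients fixed
#' at 1, with Adam at its default parameters.
#'
#' @param p_a Acceptance probability of the rerandomization being
#'   approximated, in (0, 1].
#' @param batch Minibatch size per training iteration.
#' @param b_init,b_stop,b_loss Sizes of the initialization weight pool,
#'   the early-stopping pools, and the pre-generated allocation pool.
#' @param n_init Identity-initialization steps.
#' @param n_train Maximum training iterations.
#' @param n_stop Early-stopping patience, counted in evaluations.
#' @param eval_every Iterations between stopping-metric evaluations
#'   (per-iteration evaluation would make the patience window far too
#'   sensitive to SGD noise).
#' @param lambda1,lambda2 Regularization coefficients.
#' @param hidden,dropout Network width and dropout rate.
#' @param lr,lr_gamma Adam learning rates for the parameters and the log
#'   bandwidth.
#' @param improve_tol Minimum absolute KS-metric decrease that counts as
#'   an improvement (the KS statistic on `b_stop` values has resolution
#'   of order 1e-3).
#' @param keep_best Return the parameters achieving the best stopping
#'   metric (default) rather than the final iterate.
#' @param verbose Print a line at each evaluation checkpoint?
#' @return A list of class `qrer_config`.
#' @export
qrer_config <- function(p_a = 0.1, batch = 512,
                        b_init = 1000, b_stop = 1000, b_loss = 10000,
                        n_init = 500, n_train = 5000, n_stop = 15,
                        eval_every = 100, lambda1 = 1, lambda2 = 1,
                        hidden = 512, dropout = 0.5,
                        lr = 1e-3, lr_gamma = 1e-3,
                        improve_tol = 1e-4, keep_best = TRUE,
                        verbose = FALSE) {
  cfg <- list(p_a = p_a, batch = batch, b_init = b_init, b_stop = b_stop,
              b_loss = b_loss, n_init = n_init, n_train = n_train,
              n_stop = n_stop, eval_every = eval_every,
              lambda1 = lambda1, lambda2 = lambda2, hidden = hidden,
              dropout = dropout, lr = lr, lr_gamma = lr_gamma,
              improve_tol = improve_tol, keep_best = keep_best,
              verbose = verbose)
  counts <- c("batch", "b_init", "b_stop", "b_loss", "n_init", "n_train",
              "n_stop", "eval_every", "hidden")
  if (any(unlist(cfg[counts]) < 1)) abort("all counts must be positive")
  if (lambda1 < 0 || lambda2 < 0) abort("lambda1 and lambda2 must be nonnegative")
  if (p_a <= 0 || p_a > 1) abort("`p_a` must lie in (0, 1]")
  structure(cfg, class = "qrer_config")
}

#' Early-stopping metric: KS distance between balance distributions
#'
#' The two-sample Kolmogorov-Smirnov statistic between the weighted
#' Mahalanobis distances of the generator's outputs on a fixed pool of
#' Dirichlet draws and the distances of a fixed pool of accepted
#' allocations. The generator forward pass keeps dropout active, exactly
#' as at generation time, so the metric evaluates the weights the
#' estimators will actually use.
#'
#' @param model A `qrer_generator`.
#' @param data A [qrer_data] object.
#' @param stop_weights Fixed matrix of Dirichlet weight vectors.
#' @param d_t_stop Mahalanobis distances of the fixed accepted
#'   allocations.
#' @return A number in \[0, 1\].
#' @export
stopping_metric <- function(model, data, stop_weights, d_t_stop) {
  Wt <- forward_generator(model, stop_weights, dropout_active = TRUE)
  d_w <- weighted_mahalanobis_batch(data, Wt)
  ks_statistic(d_w, d_t_stop)
}

#' Train the quasi-rerandomization generator
#'
#' Runs the full training procedure: pre-generate the allocation pools
#' and Dirichlet pools, initialize the network toward the identity map,
#' then iterate minibatch Adam steps on the MMD + regularizer objective
#' (allocations resampled with replacement from the pre-generated pool,
#' fresh Dirichlet draws every iteration, one bandwidth ascent step per
#' iteration), evaluating the KS stopping metric every `eval_every`
#' iterations and stopping after `n_stop` evaluations without
#' improvement. The parameters achieving the best metric are returned.
#'
#' All randomness is taken from R's RNG stream, so a `set.seed()` call
#' before training makes the run reproducible.
#'
#' @param data A [qrer_data] object.
#' @param config A [qrer_config].
#' @return A trained `qrer_generator`; `train_state` holds the iteration
#'   count, the best and initial stopping metrics, and the per-iteration
#'   trace (a tibble with `iteration`, `mmd`, `r1`, `r2`, `gamma`,
#'   `ks_metric`).
#' @export
train_qrer <- function(data, config = qrer_config()) {
  stopifnot(inherits(data, "qrer_data"), inherits(config, "qrer_config"))
  n1 <- data$n1; n0 <- data$n0
  ab <- arm_blocks(data)
  xbar <- colMeans(data$X)

  # pre-generated pools
  pool <- rerandomize(data, config$p_a, config$b_loss)
  stop_pool <- rerandomize(data, config$p_a, config$b_stop)
  stop_weights <- sample_dirichlet_weights(n1, n0, config$b_stop)
  init_weights <- sample_dirichlet_weights(n1, n0, config$b_init)

  model <- build_generator(n1, n0, hidden = config$hidden,
                           dropout = config$dropout,
                           lr = config$lr, lr_gamma = config$lr_gamma)
  model <- initialize_identity(model, init_weights, n_steps = config$n_init)
  ptr <- generator_ptr(model)
  net_reset_adam(ptr)

  # median-heuristic bandwidth from a first batch of allocation deltas
  idx0 <- sample.int(config$b_loss, min(config$batch, config$b_loss),
                     replace = TRUE)
  d2 <- pdist2(pool$Delta[idx0, , drop = FALSE],
               pool$Delta[idx0, , drop = FALSE])
  med <- stats::median(d2[upper.tri(d2)])
  log_gamma0 <- if (is.finite(med) && med > 0) -log(med) else 0
  net_set_log_gamma(ptr, log_gamma0)

  metric0 <- stopping_metric(model, data, stop_weights, stop_pool$D)
  best_metric <- metric0
  best_params <- net_get_params(ptr)
  best_gamma <- exp(log_gamma0)
  stall <- 0L

  nt <- config$n_train
  trace <- list(mmd = numeric(nt), r1 = numeric(nt), r2 = numeric(nt),
                gamma = numeric(nt), ks = rep(NA_real_, nt))
  it <- 0L
  while (it < nt) {
    it <- it + 1L
    idx <- sample.int(config$b_loss, config$batch, replace = TRUE)
    Wb <- sample_dirichlet_weights(n1, n0, config$batch)
    m <- dropout_masks(config$batch, config$hidden, config$dropout)
    res <- net_train_step(ptr, Wb, m$M1, m$M2,
                          pool$Delta[idx, , drop = FALSE],
                          ab$X1, ab$X0, xbar,
                          config$lambda1, config$lambda2, TRUE)
    if (!all(is.finite(res[1:3]))) {
      abort(paste0("nonfinite training loss at iteration ", it))
    }
    trace$mmd[it] <- res[1]; trace$r1[it] <- res[2]
    trace$r2[it] <- res[3]; trace$gamma[it] <- res[4]

    if (it %% config$eval_every == 0) {
      model$env$ptr <- ptr
      ks <- stopping_metric(model, data, stop_weights, stop_pool$D)
      trace$ks[it] <- ks
      if (isTRUE(config$verbose)) {
        message(sprintf("iter %d  mmd %.4f  r1 %.4g  r2 %.4g  gamma %.3g  ks %.4f",
                        it, res[1], res[2], res[3], res[4], ks))
      }
      if (ks < best_metric - config$improve_tol) {
        best_metric <- ks
        best_params <- net_get_params(ptr)
        best_gamma <- exp(net_get_log_gamma(ptr))
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= config$n_stop) break
    }
  }

  if (isTRUE(config$keep_best)) {
    net_set_params(ptr, best_params)
    net_set_log_gamma(ptr, log(best_gamma))
  }
  model <- snapshot_generator(model)
  model$train_state <- list(
    trained = TRUE,
    iterations = it,
    metric0 = metric0,
    best_metric = best_metric,
    stopped_early = it < nt,
    init_loss = model$train_state$init_loss,
    trace = tibble::tibble(
      iteration = seq_len(it),
      mmd = trace$mmd[seq_len(it)],
      r1 = trace$r1[seq_len(it)],
      r2 = trace$r2[seq_len(it)],
      gamma = trace$gamma[seq_len(it)],
      ks_metric = trace$ks[seq_len(it)]
    )
  )
  model
}
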