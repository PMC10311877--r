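#' Fit quasi-rerandomization weights to observational data
#'
#' The front door of the package: takes a unit-level data frame, runs
#' rerandomization on the covariates to build the balance template, and
#' trains the generative weight transformation so the weighted covariate
#' mean differences match, in distribution, those of the rerandomized
#' allocations. Outcomes are never consulted during fitting, preserving
#' the separation between the design and analysis stages.
#'
#' @param data A data frame with one row per unit.
#' @param treatment Bare name (or string) of the binary treatment column.
#' @param covariates Character vector of covariate columns; defaults to
#'   all numeric columns except the treatment.
#' @param p_a Acceptance probability of the rerandomization being
#'   approximated.
#' @param standardize Standardize covariates before fitting (recommended:
#'   the kernel loss is not scale-invariant).
#' @param config A [qrer_config]; its `p_a` is overridden by the `p_a`
#'   argument.
#' @param ... Passed to [qrer_config] when `config` is not supplied.
#' @return An object of class `qrer_fit` bundling the data container, the
#'   trained generator and the configuration.
#' @examples
#' \donttest{
#' d <- simulate_qrer_study(scenario = 1, r = 1, seed = 1)
#' set.seed(7)
#' fit <- qrer(d, treated, covariates = paste0("x", 1:8),
#'             p_a = 0.5, n_train = 200, n_init = 50, b_loss = 2000)
#' glance(fit)
#' est <- estimate_effect(fit, y_linear)
#' est
#' }
#' @export
qrer <- function(data, treatment, covariates = NULL, p_a = 0.1,
                 standardize = TRUE, config = NULL, ...) {
  tq <- rlang::enquo(treatment)
  qd <- qrer_data(data, treatment = !!tq, covariates = covariates,
                  standardize = standardize)
  if (is.null(config)) config <- qrer_config(p_a = p_a, ...)
  config$p_a <- p_a
  model <- train_qrer(qd, config)
  structure(
    list(data = qd, model = model, config = config, frame = data,
         treatment_col = rlang::as_name(tq)),
    class = "qrer_fit"
  )
}

#' @export
print.qrer_fit <- function(x, ...) {
  cat("<qrer_fit> quasi-rerandomization weights, p_a = ", x$config$p_a,
      "\n", sep = "")
  print(x$data)
  ts <- x$model$train_state
  cat("  trained ", ts$iterations, " iterations; KS stopping metric ",
      signif(ts$metric0, 3), " -> ", signif(ts$best_metric, 3), "\n", sep = "")
  invisible(x)
}

#' Estimate the treatment effect from a fitted model
#'
#' Generates transformed weight vectors from the trained generator and
#' applies the weighted difference-in-means estimator, with
#' heteroskedasticity-robust standard errors from a weighted linear
#' model. The ensemble estimator uses the average of `m` weight vectors
#' (identical to averaging the per-vector estimates); the single-vector
#' estimator (`m = 1`) mimics inference in a rerandomized experiment with
#' one accepted allocation.
#'
#' @param fit A `qrer_fit`.
#' @param outcome Bare name of an outcome column in the original data, or
#'   a numeric vector in the original row order.
#' @param m Number of weight vectors to ensemble (1 = single-vector).
#' @param level Confidence level.
#' @param vcov_type Sandwich flavor (see [pate_inference]).
#' @return A one-row tibble: `estimator`, `m`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `level`.
#' @export
estimate_effect <- function(fit, outcome, m = 1000, level = 0.95,
                            vcov_type = "HC1") {
  stopifnot(inherits(fit, "qrer_fit"))
  oq <- rlang::enquo(outcome)
  y <- rlang::eval_tidy(oq, data = fit$frame)
  if (!is.numeric(y) || length(y) != fit$data$n) {
    abort("`outcome` must resolve to a numeric vector with one value per unit")
  }
  y_canon <- y[fit$data$perm]
  W <- generate_weights(fit$model, m = m)
  w_avg <- colMeans(W)
  res <- pate_inference(w_avg, fit$data$t_obs, y_canon,
                        level = level, vcov_type = vcov_type)
  dplyr::bind_cols(
    tibble::tibble(estimator = if (m == 1) "QReR_S" else "QReR_M", m = m),
    res
  )
}

#' @describeIn qrer Per-unit average generated weight, original row
#'   order.
#' @param x A `qrer_fit`.
#' @param m Number of generated weight vectors averaged.
#' @method tidy qrer_fit
#' @export
tidy.qrer_fit <- function(x, m = 1000, ...) {
  W <- generate_weights(x$model, m = m)
  weights_tibble(x$data, W)
}

#' @describeIn qrer One-row training summary.
#' @method glance qrer_fit
#' @export
glance.qrer_fit <- function(x, ...) {
  ts <- x$model$train_state
  tibble::tibble(
    n = x$data$n, n1 = x$data$n1, n0 = x$data$n0,
    d = ncol(x$data$X), p_a = x$config$p_a,
    iterations = ts$iterations,
    ks_initial = ts$metric0,
    ks_best = ts$best_metric,
    gamma = exp(x$model$log_gamma),
    stopped_early = ts$stopped_early
  )
}

#' Diagnostic plots for a fitted model
#'
#' `type = "trace"` shows the MMD loss and the KS stopping metric over
#' training iterations; `type = "balance"` compares, covariate by
#' covariate, the distribution of weighted mean differences from the
#' generator with that of accepted rerandomized allocations.
#'
#' @param object A `qrer_fit`.
#' @param type `"trace"` or `"balance"`.
#' @param n_vectors Number of weight vectors / allocations for the
#'   balance panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qrer_fit
#' @export
autoplot.qrer_fit <- function(object, type = c("trace", "balance"),
                              n_vectors = 500, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- object$model$train_state$trace
    df <- dplyr::bind_rows(
      tibble::tibble(iteration = tr$iteration, value = tr$mmd,
                     series = "MMD loss"),
      tr |>
        dplyr::filter(!is.na(.data$ks_metric)) |>
        dplyr::transmute(iteration = .data$iteration,
                         value = .data$ks_metric,
                         series = "KS stopping metric")
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "iteration", y = NULL,
                    title = "Quasi-rerandomization training")
  } else {
    bal <- balance_comparison(object, n_vectors = n_vectors, deltas = TRUE)
    ggplot2::ggplot(bal,
                    ggplot2::aes(.data$covariate, .data$delta,
                                 fill = .data$source)) +
      ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.3) +
      ggplot2::labs(x = NULL, y = "covariate mean difference",
                    fill = NULL,
                    title = "Weighted vs rerandomized balance")
  }
}
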