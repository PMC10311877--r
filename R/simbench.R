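scenario_params <- function(scenario) {
  mu <- c(0.2, 0.2, 0.5, 0.5)
  switch(as.character(scenario),
    "1" = list(mu = mu, Sigma = diag(4)),
    "2" = list(mu = sqrt(1.5) * mu, Sigma = 2 * diag(4)),
    "3" = list(mu = sqrt(1.5) * mu,
               Sigma = 1.5 * diag(4) + 0.5 * matrix(1, 4, 4)),
    abort("`scenario` must be 1, 2 or 3")
  )
}

# response surface on the RAW covariate scale
g_surface <- function(X, surface) {
  gl <- 3.5 * X[, 1] + 4.5 * X[, 3] + 1.5 * X[, 5] + 2.5 * X[, 7]
  if (surface == "linear") return(gl)
  gi <- gl + 2.5 * sign(X[, 1]) * sqrt(abs(X[, 1])) + 2.5 * X[, 3] * X[, 7]
  if (surface == "interaction") return(gi)
  if (surface == "polynomial") {
    return(gi + 5.5 * X[, 3]^2 - 4.5 * X[, 1] * X[, 3]^3)
  }
  abort("`surface` must be 'linear', 'interaction' or 'polynomial'")
}

#' Simulate an observational study with treatment-dependent covariates
#'
#' Generates the benchmark design: 250 treated units and `r * 250`
#' controls with 8 covariates. The four Gaussian covariates are
#' `N(mu, Sigma)` among the treated and standard normal among controls,
#' with three scenarios for `(mu, Sigma)` (homogeneous variance,
#' heterogeneous variance, correlated treated covariates); two pairs of
#' Bernoulli covariates have success rates `0.1 + 0.068 T` and
#' `0.4 + 0.242 T`, so every covariate has a true standardized mean
#' difference of 0.2 or 0.5. Three responses per unit follow
#' `Y = g(X) + tau T + eps`, `eps ~ N(0, 1)` shared across the linear,
#' interaction and polynomial surfaces, computed from the raw
#' covariates. Standardized copies of the covariates are attached as
#' `x*_std` columns.
#'
#' The `r = 2` control pool is always generated in full and the `r = 1`
#' dataset keeps its first 250 controls, so for a fixed `seed` the
#' `r = 1` dataset is a row subset of the `r = 2` dataset.
#'
#' @param scenario Covariate scenario, 1, 2 or 3.
#' @param r Control-to-treated ratio, 1 or 2.
#' @param seed Optional integer seed (uses and advances R's RNG when
#'   `NULL`).
#' @param tau Additive treatment effect.
#' @return A tibble with `unit_id`, `treated`, raw covariates `x1..x8`,
#'   standardized copies `x1_std..x8_std` and outcomes `y_linear`,
#'   `y_interaction`, `y_polynomial`; attributes `scenario`, `r`, `tau`,
#'   `seed`.
#' @examples
#' d <- simulate_qrer_study(scenario = 1, r = 1, seed = 42)
#' dplyr::count(d, treated)
#' @export
simulate_qrer_study <- function(scenario = 1, r = 1, seed = NULL, tau = 1) {
  if (!r %in% c(1, 2)) abort("`r` must be 1 or 2")
  if (!scenario %in% 1:3) abort("`scenario` must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  sp <- scenario_params(scenario)
  n1 <- 250L
  n0_full <- 500L  # full control pool; r = 1 keeps the first half

  R <- chol(sp$Sigma)
  Xt_g <- matrix(rnorm(n1 * 4), n1, 4) %*% R
  Xt_g <- sweep(Xt_g, 2, sp$mu, "+")
  Xc_g <- matrix(rnorm(n0_full * 4), n0_full, 4)
  Xt_b <- cbind(matrix(rbinom(n1 * 2, 1, 0.168), n1, 2),
                matrix(rbinom(n1 * 2, 1, 0.642), n1, 2))
  Xc_b <- cbind(matrix(rbinom(n0_full * 2, 1, 0.1), n0_full, 2),
                matrix(rbinom(n0_full * 2, 1, 0.4), n0_full, 2))
  X <- rbind(cbind(Xt_g, Xt_b[, c(1, 2)], Xt_b[, c(3, 4)]),
             cbind(Xc_g, Xc_b[, c(1, 2)], Xc_b[, c(3, 4)]))
  colnames(X) <- paste0("x", 1:8)
  # interleave binary pairs into positions 5..8 (x5,x6 rare; x7,x8 common)
  eps <- rnorm(n1 + n0_full)

  keep <- seq_len(n1 + r * 250L)
  X <- X[keep, , drop = FALSE]
  eps <- eps[keep]
  t_obs <- c(rep(1L, n1), rep(0L, r * 250L))

  ys <- lapply(c("linear", "interaction", "polynomial"), function(s) {
    g_surface(X, s) + tau * t_obs + eps
  })

  out <- tibble::as_tibble(as.data.frame(X))
  out <- dplyr::mutate(out,
                       unit_id = seq_along(t_obs), treated = t_obs,
                       y_linear = ys[[1]], y_interaction = ys[[2]],
                       y_polynomial = ys[[3]],
                       .before = 1)
  out <- standardize_covariates(out, paste0("x", 1:8))
  attr(out, "scenario") <- scenario
  attr(out, "r") <- r
  attr(out, "tau") <- tau
  attr(out, "seed") <- seed
  out
}

#' Standardize covariate columns
#'
#' Adds `_std` copies of the given columns, centred and scaled to unit
#' sample variance (n-1 denominator). Constant columns are an error.
#'
#' @param data A data frame.
#' @param cols Character vector of column names.
#' @return `data` with additional `<col>_std` columns.
#' @export
standardize_covariates <- function(data, cols) {
  for (cl in cols) {
    v <- data[[cl]]
    s <- sd(v)
    if (s == 0) abort(paste0("column '", cl, "' is constant and cannot be standardized"))
    data[[paste0(cl, "_std")]] <- (v - mean(v)) / s
  }
  data
}

#' Regenerate responses under a new allocation
#'
#' Recomputes `Y = g(X) + tau T + eps` from the raw covariates of a
#' simulated study for a candidate allocation, with fresh noise --- what a
#' rerandomized experiment would observe had it assigned `allocation`.
#'
#' @param data A tibble from [simulate_qrer_study].
#' @param allocation Binary vector in the row order of `data`.
#' @param surface `"linear"`, `"interaction"` or `"polynomial"`.
#' @param tau Additive treatment effect.
#' @return Numeric outcome vector.
#' @export
simulate_responses <- function(data, allocation, surface, tau = 1) {
  X <- as.matrix(data[, paste0("x", 1:8)])
  g_surface(X, surface) + tau * allocation + rnorm(nrow(X))
}

#' True standardized mean differences of the design
#'
#' Closed-form standardized mean differences
#' `(mu_T - mu_C) / sqrt((sigma2_T + sigma2_C) / 2)` implied by the
#' generative parameters of a covariate scenario.
#'
#' @param scenario Covariate scenario.
#' @return A tibble with `covariate` and `smd`.
#' @export
design_smd <- function(scenario = 1) {
  sp <- scenario_params(scenario)
  smd_g <- sp$mu / sqrt((diag(sp$Sigma) + 1) / 2)
  smd_b <- function(pt, pc) (pt - pc) / sqrt((pt * (1 - pt) + pc * (1 - pc)) / 2)
  tibble::tibble(
    covariate = paste0("x", 1:8),
    smd = c(smd_g, rep(smd_b(0.168, 0.1), 2), rep(smd_b(0.642, 0.4), 2))
  )
}

#' Benchmark the rerandomized-experiment estimator
#'
#' For each replicate: simulate a study, draw one accepted allocation at
#' `p_a`, regenerate responses under it, and take the raw difference in
#' means. No network training is involved.
#'
#' @param scenario,r Design cell.
#' @param surfaces Response surfaces to evaluate (responses share the
#'   per-unit noise draw within a replicate).
#' @param p_a Acceptance probability (may be a vector).
#' @param n_reps Number of replicates.
#' @param tau True effect.
#' @return A tibble of per-replicate estimates with columns `scenario`,
#'   `r`, `surface`, `p_a`, `method`, `rep`, `estimate`, `error`.
#' @export
run_rer_benchmark <- function(scenario = 1, r = 1,
                              surfaces = c("linear", "interaction", "polynomial"),
                              p_a = 0.1, n_reps = 200, tau = 1) {
  out <- vector("list", n_reps * length(p_a) * length(surfaces))
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    d <- simulate_qrer_study(scenario = scenario, r = r, tau = tau)
    qd <- qrer_data(d, treated, covariates = paste0("x", 1:8),
                    standardize = TRUE)
    for (pa in p_a) {
      pool <- rerandomize(qd, pa, 1)
      t_orig <- as.integer(pool$T[1, ])[order(qd$perm)]
      eps <- rnorm(qd$n)
      X <- as.matrix(d[, paste0("x", 1:8)])
      for (s in surfaces) {
        y <- g_surface(X, s) + tau * t_orig + eps
        est <- mean(y[t_orig == 1]) - mean(y[t_orig == 0])
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          scenario = scenario, r = r, surface = s, p_a = pa,
          method = "ReR", rep = rep_i, estimate = est, error = est - tau
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Benchmark the quasi-rerandomization estimators
#'
#' For each replicate: simulate a study, train the generator on the
#' standardized covariates and observed allocation, and estimate the
#' effect from the observed responses with the single-vector and
#' ensembled estimators.
#'
#' @inheritParams run_rer_benchmark
#' @param p_a Single acceptance probability.
#' @param config A [qrer_config] used for every fit.
#' @param m Ensemble size for the `QReR_M` estimator.
#' @return A tibble of per-replicate estimates (methods `QReR_S` and
#'   `QReR_M`).
#' @export
run_qrer_benchmark <- function(scenario = 1, r = 1,
                               surfaces = "linear",
                               p_a = 0.1, n_reps = 20,
                               config = qrer_config(),
                               m = 1000, tau = 1) {
  out <- vector("list", 0)
  for (rep_i in seq_len(n_reps)) {
    d <- simulate_qrer_study(scenario = scenario, r = r, tau = tau)
    cfg <- config
    cfg$p_a <- p_a
    qd <- qrer_data(d, treated, covariates = paste0("x", 1:8),
                    standardize = TRUE)
    model <- train_qrer(qd, cfg)
    W <- generate_weights(model, m = m)
    w_single <- W[1, ]
    w_avg <- colMeans(W)
    y_canon <- lapply(surfaces, function(s) d[[paste0("y_", s)]][qd$perm])
    for (j in seq_along(surfaces)) {
      for (meth in c("QReR_S", "QReR_M")) {
        w <- if (meth == "QReR_S") w_single else w_avg
        est <- tau_hat(w, qd$t_obs, y_canon[[j]])
        out[[length(out) + 1]] <- tibble::tibble(
          scenario = scenario, r = r, surface = surfaces[j], p_a = p_a,
          method = meth, rep = rep_i, estimate = est, error = est - tau
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate a benchmark into bias, RMSE and Monte Carlo standard errors
#'
#' `bias = mean(error)`, `rmse = sqrt(mean(error^2))`;
#' `mcse_bias = sd(estimate) / sqrt(K)` and
#' `mcse_rmse = sqrt(var(error^2) / (4 K rmse^2))` (delta method), the
#' standard simulation-study formulas.
#'
#' @param results Per-replicate tibble from [run_rer_benchmark] or
#'   [run_qrer_benchmark].
#' @return One row per design cell and method.
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::group_by(.data$scenario, .data$r, .data$surface, .data$p_a,
                    .data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      bias = mean(.data$error),
      rmse = sqrt(mean(.data$error^2)),
      mcse_bias = sd(.data$estimate) / sqrt(dplyr::n()),
      mcse_rmse = sqrt(var(.data$error^2) / (4 * dplyr::n() * mean(.data$error^2))),
      .groups = "drop"
    )
}

#' Covariate-level balance comparison against rerandomization
#'
#' Generates weight vectors from a trained model and accepted
#' allocations from the rerandomization engine, and compares -- for each
#' covariate -- the distribution of weighted mean differences with the
#' allocation mean differences by the two-sample Kolmogorov-Smirnov
#' statistic and its asymptotic p-value.
#'
#' @param fit A `qrer_fit` (or a `qrer_generator` plus `data`).
#' @param n_vectors Number of weight vectors and allocations.
#' @param deltas If `TRUE`, return the raw long tibble of mean
#'   differences instead of the per-covariate KS summary.
#' @param data A [qrer_data] when `fit` is a bare generator.
#' @return A tibble with `covariate`, `ks_statistic`, `p_value` (or the
#'   long delta tibble when `deltas = TRUE`).
#' @export
balance_comparison <- function(fit, n_vectors = 1000, deltas = FALSE,
                               data = NULL) {
  if (inherits(fit, "qrer_fit")) {
    model <- fit$model
    data <- fit$data
    p_a <- fit$config$p_a
  } else {
    stopifnot(inherits(fit, "qrer_generator"), inherits(data, "qrer_data"))
    model <- fit
    p_a <- fit$train_state$p_a %||% 0.1
  }
  W <- generate_weights(model, m = n_vectors)
  d_w <- weighted_mean_difference(data, W)
  pool <- rerandomize(data, p_a, n_vectors)
  cov_names <- colnames(data$X) %||% paste0("x", seq_len(ncol(data$X)))
  if (deltas) {
    long <- function(M, src) {
      tibble::tibble(
        covariate = rep(cov_names, each = nrow(M)),
        delta = as.vector(M),
        source = src
      )
    }
    return(dplyr::bind_rows(long(d_w, "QReR"), long(pool$Delta, "ReR")))
  }
  purrr::map_dfr(seq_along(cov_names), function(j) {
    kt <- suppressWarnings(ks.test(d_w[, j], pool$Delta[, j], exact = FALSE))
    tibble::tibble(covariate = cov_names[j],
                   ks_statistic = unname(kt$statistic),
                   p_value = unname(kt$p.value))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
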