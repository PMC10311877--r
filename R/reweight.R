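#' Flat Dirichlet weights on the two arm simplices
#'
#' Draws `n_draws` weight vectors whose treated block is flat Dirichlet on
#' the `n1`-simplex and whose control block is independently flat
#' Dirichlet on the `n0`-simplex (each block sums to one). Implemented as
#' normalized unit-rate exponential draws.
#'
#' @param n1,n0 Arm sizes.
#' @param n_draws Number of vectors to draw.
#' @return A `n_draws` by `n1 + n0` matrix, one weight vector per row in
#'   canonical (treated-first) order.
#' @examples
#' W <- sample_dirichlet_weights(3, 4, n_draws = 2)
#' rowSums(W[, 1:3])  # both 1
#' @export
sample_dirichlet_weights <- function(n1, n0, n_draws = 1) {
  if (n1 < 1 || n0 < 1) abort("`n1` and `n0` must be at least 1")
  G1 <- matrix(rexp(n_draws * n1), n_draws, n1)
  G0 <- matrix(rexp(n_draws * n0), n_draws, n0)
  cbind(G1 / rowSums(G1), G0 / rowSums(G0))
}

# validate a weight matrix (rows = draws) against a qrer_data container
check_weights <- function(data, W, tol = .simplex_tol) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  if (ncol(W) != data$n) {
    abort(paste0("weight vectors have length ", ncol(W),
                 " but the data have ", data$n, " units"))
  }
  if (any(W < 0)) abort("weights must be nonnegative")
  s1 <- rowSums(W[, seq_len(data$n1), drop = FALSE])
  s0 <- rowSums(W[, data$n1 + seq_len(data$n0), drop = FALSE])
  if (any(abs(s1 - 1) > tol) || any(abs(s0 - 1) > tol)) {
    abort(paste0("weights must sum to 1 within each arm (tolerance ",
                 format(tol), "); renormalize explicitly if intended"))
  }
  W
}

#' Weighted covariate mean difference
#'
#' For a weight vector `w` (treated block summing to 1, control block
#' summing to 1), the weighted mean difference is
#' `sum_i w_i T_i X_i - sum_i w_i (1 - T_i) X_i`. With uniform weights it
#' reduces to the plain difference of arm means; it is linear in `w`.
#'
#' @param data A [qrer_data] object.
#' @param weights A weight vector of length `n`, or a matrix with one
#'   vector per row, in canonical order.
#' @return A length-`d` vector (or a matrix with one row per weight
#'   vector).
#' @export
weighted_mean_difference <- function(data, weights) {
  stopifnot(inherits(data, "qrer_data"))
  single <- is.null(dim(weights))
  W <- check_weights(data, weights)
  ab <- arm_blocks(data)
  Delta <- W[, seq_len(data$n1), drop = FALSE] %*% ab$X1 -
    W[, data$n1 + seq_len(data$n0), drop = FALSE] %*% ab$X0
  if (single) drop(Delta) else Delta
}

#' Weighted Mahalanobis distance
#'
#' Plugs weighted mean and covariance estimators into the rerandomization
#' balance measure. With `w*_i = (n1 T_i + n0 (1 - T_i)) w_i / n`, the
#' weighted covariance is
#' `cov_w(X) = sum_i w*_i (X_i - xbar_w)(X_i - xbar_w)' / (1 - sum_i w*_i^2)`
#' and the distance is `(n1 n0 / n) delta' cov_w(X)^-1 delta` with `delta`
#' the weighted mean difference. Under uniform weights this equals the
#' allocation-based Mahalanobis distance exactly.
#'
#' @inheritParams weighted_mean_difference
#' @return For a single weight vector, a list with `delta`, `d_w` and
#'   `w_star`; for a matrix of weight vectors, a numeric vector of
#'   distances.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), treated = c(1, 1, 0, 0))
#' qd <- qrer_data(d, treated)
#' weighted_mahalanobis(qd, rep(0.5, 4))$d_w  # 2.4, as for the allocation
#' @export
weighted_mahalanobis <- function(data, weights) {
  stopifnot(inherits(data, "qrer_data"))
  single <- is.null(dim(weights))
  W <- check_weights(data, weights)
  d_w <- weighted_mahalanobis_batch(data, W)
  if (!single) return(d_w)
  s <- c(rep(data$n1, data$n1), rep(data$n0, data$n0)) / data$n
  list(
    delta = weighted_mean_difference(data, weights),
    d_w = d_w[1],
    w_star = drop(W) * s
  )
}

# Batched computation of the weighted Mahalanobis distance for a matrix of
# weight vectors (rows). The second-moment matrices for all rows come from
# a single GEMM against the d^2 column products of X.
weighted_mahalanobis_batch <- function(data, W) {
  n1 <- data$n1; n0 <- data$n0; n <- data$n
  d <- ncol(data$X)
  s <- c(rep(n1, n1), rep(n0, n0)) / n
  Wstar <- sweep(W, 2, s, "*")  # rows sum to 1 exactly
  ssq <- rowSums(Wstar^2)
  if (any(ssq >= 1)) {
    abort("degenerate weights: sum of squared pooled weights >= 1 (all mass on one unit)")
  }
  Delta <- weighted_mean_difference(data, W)
  if (is.null(dim(Delta))) Delta <- matrix(Delta, nrow = 1)
  # Z: n x d^2 columnwise products X_j * X_k
  Z <- data$X[, rep(seq_len(d), times = d), drop = FALSE] *
    data$X[, rep(seq_len(d), each = d), drop = FALSE]
  M2 <- Wstar %*% Z                 # B x d^2 second moments
  Xbar <- Wstar %*% data$X          # B x d weighted means
  out <- numeric(nrow(W))
  for (b in seq_len(nrow(W))) {
    Cw <- matrix(M2[b, ], d, d) - tcrossprod(Xbar[b, ])
    Cw <- Cw / (1 - ssq[b])
    ch <- tryCatch(chol(Cw), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch)) / max(diag(ch)) < 1e-6) {
      abort("weighted covariance matrix is singular (weights too concentrated)")
    }
    v <- backsolve(ch, forwardsolve(t(ch), Delta[b, ]))
    out[b] <- n1 * n0 / n * sum(Delta[b, ] * v)
  }
  out
}

#' Tidy per-unit weights
#'
#' Converts a weight vector (or the column means of a weight matrix) back
#' to the original row order of the data used to build the container.
#'
#' @param data A [qrer_data] object.
#' @param weights A weight vector or matrix in canonical order.
#' @return A tibble with `unit_id`, `treated` and `weight` columns in the
#'   original data order (weights on the within-arm simplex scale).
#' @export
weights_tibble <- function(data, weights) {
  if (!is.null(dim(weights))) weights <- colMeans(weights)
  weights <- drop(check_weights(data, weights))
  inv <- order(data$perm)
  tibble::tibble(
    unit_id = data$unit_id[inv],
    treated = data$t_obs[inv],
    weight = weights[inv]
  )
}
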