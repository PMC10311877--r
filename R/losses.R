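#' Radial basis function kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive bandwidth.
#' @return A number in (0, 1].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a positive number")
  }
  exp(-gamma * sum((x - y)^2))
}

# pairwise squared Euclidean distances between rows of A and rows of B
pdist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- -2 * tcrossprod(A, B)
  D <- sweep(sweep(D, 1, an, "+"), 2, bn, "+")
  pmax(D, 0)
}

#' Kernel maximum mean discrepancy between two delta samples
#'
#' The square root of the biased (V-statistic) MMD^2 between two samples
#' of covariate mean-difference vectors under an RBF kernel; diagonal
#' terms are included, and the value is clamped at zero before the root.
#' Zero when the two samples coincide.
#'
#' @param deltas_w,deltas_t Matrices with one delta vector per row (a
#'   plain vector is treated as a one-column sample).
#' @param gamma Positive RBF bandwidth.
#' @return A nonnegative number.
#' @examples
#' mmd_loss(matrix(0), matrix(1), gamma = 1)  # sqrt(2 - 2 * exp(-1))
#' @export
mmd_loss <- function(deltas_w, deltas_t, gamma) {
  if (is.null(dim(deltas_w))) deltas_w <- matrix(deltas_w, ncol = 1)
  if (is.null(dim(deltas_t))) deltas_t <- matrix(deltas_t, ncol = 1)
  if (nrow(deltas_w) != nrow(deltas_t) || ncol(deltas_w) != ncol(deltas_t)) {
    abort("the two delta samples must have identical dimensions")
  }
  if (gamma <= 0) abort("`gamma` must be positive")
  B <- nrow(deltas_w)
  v <- (sum(exp(-gamma * pdist2(deltas_w, deltas_w))) +
          sum(exp(-gamma * pdist2(deltas_t, deltas_t))) -
          2 * sum(exp(-gamma * pdist2(deltas_w, deltas_t)))) / B^2
  sqrt(max(v, 0))
}

#' Balance regularizer: weighted arm means against the pooled mean
#'
#' Mean over weight vectors of the squared distances between each
#' weighted arm mean and the pooled covariate mean `xbar`. Zero exactly
#' when both weighted arm means reproduce the pooled mean, the balance
#' identity a rerandomized allocation satisfies approximately.
#'
#' @param data A [qrer_data] object.
#' @param weights Weight vector or matrix (rows = vectors), canonical
#'   order.
#' @return A nonnegative number.
#' @export
regularizer_balance <- function(data, weights) {
  W <- check_weights(data, weights)
  ab <- arm_blocks(data)
  xbar <- colMeans(data$X)
  M1 <- sweep(W[, seq_len(data$n1), drop = FALSE] %*% ab$X1, 2, xbar, "-")
  M0 <- sweep(W[, data$n1 + seq_len(data$n0), drop = FALSE] %*% ab$X0, 2, xbar, "-")
  (sum(M1^2) + sum(M0^2)) / nrow(W)
}

#' Dispersion regularizer: distance of weights from uniform
#'
#' Mean over weight vectors of the squared distances of the treated and
#' control weight blocks from the uniform weights `1/n1` and `1/n0`.
#' Guards against extreme weights; zero iff every vector is uniform.
#'
#' @param weights Weight vector or matrix in canonical order.
#' @param n1,n0 Arm sizes.
#' @return A nonnegative number.
#' @export
regularizer_dispersion <- function(weights, n1, n0) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (ncol(weights) != n1 + n0) abort("weight length must equal n1 + n0")
  U1 <- weights[, seq_len(n1), drop = FALSE] - 1 / n1
  U0 <- weights[, n1 + seq_len(n0), drop = FALSE] - 1 / n0
  (sum(U1^2) + sum(U0^2)) / nrow(weights)
}

#' Full training objective
#'
#' `MMD + lambda1 * R1 + lambda2 * R2` evaluated for a batch of
#' transformed weight vectors against a batch of rerandomized
#' mean-difference vectors.
#'
#' @param data A [qrer_data] object.
#' @param weights Matrix of weight vectors (rows), canonical order.
#' @param deltas_t Matrix of allocation mean-difference vectors (rows).
#' @param gamma Positive RBF bandwidth.
#' @param lambda1,lambda2 Nonnegative regularization coefficients.
#' @return A nonnegative number.
#' @export
total_loss <- function(data, weights, deltas_t, gamma,
                       lambda1 = 1, lambda2 = 1) {
  W <- check_weights(data, weights)
  mmd_loss(weighted_mean_difference(data, W), deltas_t, gamma) +
    lambda1 * regularizer_balance(data, W) +
    lambda2 * regularizer_dispersion(W, data$n1, data$n0)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the two empirical distribution
#' functions, in \[0, 1\].
#'
#' @param a,b Nonempty numeric samples.
#' @return A number in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("samples must be nonempty")
  unname(suppressWarnings(ks.test(a, b))$statistic)
}
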