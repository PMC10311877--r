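# Independent brute-force oracles and small fixtures, written directly from
# the defining formulas; deliberately loop-based and free of the package's
# vectorized code paths.

# the 4-unit, 1-covariate instance used for hand-checked values
tiny_data <- function() {
  qrer_data(data.frame(x = c(1, 2, 3, 4), treated = c(1, 1, 0, 0)), treated)
}

random_data <- function(n1 = 6, n0 = 8, d = 2) {
  df <- data.frame(matrix(rnorm((n1 + n0) * d), n1 + n0, d))
  names(df) <- paste0("x", seq_len(d))
  df$treated <- c(rep(1, n1), rep(0, n0))
  qrer_data(df, treated)
}

# Mahalanobis distance assembled term by term from means and covariance
mahalanobis_bf <- function(X, t) {
  n <- nrow(X); n1 <- sum(t); n0 <- n - n1
  delta <- colMeans(X[t == 1, , drop = FALSE]) - colMeans(X[t == 0, , drop = FALSE])
  S <- cov(X)
  drop(n1 * n0 / n * t(delta) %*% solve(S) %*% delta)
}

# weighted Mahalanobis distance, literal transcription
weighted_mahalanobis_bf <- function(X, t, w) {
  n <- nrow(X); n1 <- sum(t); n0 <- n - n1
  wstar <- (n1 * t + n0 * (1 - t)) * w / n
  xbar_w <- colSums(wstar * X)
  S <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) {
    ci <- X[i, ] - xbar_w
    S <- S + wstar[i] * tcrossprod(ci)
  }
  S <- S / (1 - sum(wstar^2))
  delta <- colSums(w * t * X) - colSums(w * (1 - t) * X)
  drop(n1 * n0 / n * t(delta) %*% solve(S) %*% delta)
}

# O(B^2) double-loop MMD with diagonal terms included
mmd_bf <- function(A, B, gamma) {
  stopifnot(nrow(A) == nrow(B))
  b <- nrow(A)
  k <- function(x, y) exp(-gamma * sum((x - y)^2))
  s <- 0
  for (i in seq_len(b)) for (j in seq_len(b)) {
    s <- s + k(A[i, ], A[j, ]) + k(B[i, ], B[j, ]) - 2 * k(A[i, ], B[j, ])
  }
  sqrt(max(s / b^2, 0))
}

# term-by-term transcriptions of the two regularizers
reg_balance_bf <- function(X, t, Wmat) {
  xbar <- colMeans(X)
  tot <- 0
  for (b in seq_len(nrow(Wmat))) {
    w <- Wmat[b, ]
    m1 <- colSums(w * t * X)
    m0 <- colSums(w * (1 - t) * X)
    tot <- tot + sum((m1 - xbar)^2) + sum((m0 - xbar)^2)
  }
  tot / nrow(Wmat)
}

reg_dispersion_bf <- function(Wmat, n1, n0) {
  tot <- 0
  for (b in seq_len(nrow(Wmat))) {
    tot <- tot + sum((Wmat[b, 1:n1] - 1 / n1)^2) +
      sum((Wmat[b, n1 + 1:n0] - 1 / n0)^2)
  }
  tot / nrow(Wmat)
}

# all C(n, n1) allocations as rows
enumerate_allocations <- function(n, n1) {
  combos <- utils::combn(n, n1)
  t(apply(combos, 2, function(ix) {
    v <- integer(n); v[ix] <- 1L; v
  }))
}

# a small, quickly trained configuration reused by the slower checks;
# any qrer_config() argument can be overridden
small_train_config <- function(...) {
  defaults <- list(p_a = 0.5, batch = 64, b_init = 100, b_stop = 200,
                   b_loss = 500, n_init = 30, n_train = 60, n_stop = 3,
                   eval_every = 20)
  do.call(qrer_config, utils::modifyList(defaults, list(...)))
}

small_sim_data <- function(n1 = 30, n0 = 30, d = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n0
  df <- as.data.frame(matrix(rnorm(n * d), n, d))
  names(df) <- paste0("x", seq_len(d))
  df$treated <- c(rep(1, n1), rep(0, n0))
  df$x1 <- df$x1 + 0.4 * df$treated  # mild confounding
  qrer_data(df, treated, covariates = paste0("x", seq_len(d)))
}
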