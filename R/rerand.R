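#' Mahalanobis threshold for a target acceptance probability
#'
#' Under complete randomization the Mahalanobis distance between arm means
#' is asymptotically chi-squared with `d` degrees of freedom, so the
#' threshold `a` solving `P(chi2_d <= a) = p_a` accepts approximately a
#' fraction `p_a` of allocations. With `p_a = 1` every allocation is
#' accepted (`a = Inf`) and rerandomization reduces to complete
#' randomization.
#'
#' @param d Number of covariates (degrees of freedom).
#' @param p_a Target acceptance probability in (0, 1].
#' @return The threshold (a nonnegative number, or `Inf` for `p_a = 1`).
#' @examples
#' chi2_threshold(8, 0.1)
#' chi2_threshold(8, 1)
#' @export
chi2_threshold <- function(d, p_a) {
  if (!is.numeric(d) || length(d) != 1 || d < 1) abort("`d` must be a positive integer")
  if (!is.numeric(p_a) || length(p_a) != 1 || p_a <= 0 || p_a > 1) {
    abort("`p_a` must lie in (0, 1]")
  }
  if (p_a == 1) return(Inf)
  qchisq(p_a, df = d)
}

#' Mahalanobis distance of a candidate allocation
#'
#' Computes `(n1 * n0 / n) * delta' S^-1 delta` where `delta` is the
#' difference of covariate means between the two arms defined by `t` and
#' `S` is the sample covariance of the covariates (n-1 denominator). The
#' distance is invariant under invertible affine maps of the covariate
#' columns.
#'
#' @param data A [qrer_data] object.
#' @param t Binary allocation vector in the canonical (treated-first)
#'   ordering of `data`, with exactly `data$n1` ones. Defaults to the
#'   observed allocation.
#' @return A single nonnegative number.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), treated = c(1, 1, 0, 0))
#' qd <- qrer_data(d, treated)
#' mahalanobis_distance(qd)  # 2.4
#' @export
mahalanobis_distance <- function(data, t = data$t_obs) {
  stopifnot(inherits(data, "qrer_data"))
  t <- as.integer(t)
  if (length(t) != data$n || !all(t %in% c(0L, 1L)) || sum(t) != data$n1) {
    abort("`t` must be binary with exactly n1 treated units")
  }
  delta <- colMeans(data$X[t == 1L, , drop = FALSE]) -
    colMeans(data$X[t == 0L, , drop = FALSE])
  as.numeric(data$n1 * data$n0 / data$n * (delta %*% data$cov_inv %*% delta))
}

#' Draw one complete-randomization allocation
#'
#' Uniform draw over all allocations with exactly `n1` treated units,
#' with its Mahalanobis distance attached.
#'
#' @param data A [qrer_data] object.
#' @return A list with elements `t` (canonical binary vector) and `d`
#'   (Mahalanobis distance).
#' @export
sample_cr_allocation <- function(data) {
  stopifnot(inherits(data, "qrer_data"))
  if (data$n1 < 1 || data$n1 > data$n - 1) {
    abort("n1 must lie in [1, n - 1]")
  }
  t <- integer(data$n)
  t[sample.int(data$n, data$n1)] <- 1L
  list(t = t, d = mahalanobis_distance(data, t))
}

# Vectorized raw draws: n_draws allocations (rows) with their distances.
cr_allocation_batch <- function(data, n_draws) {
  n <- data$n; n1 <- data$n1; n0 <- data$n0
  idx <- vapply(seq_len(n_draws), function(i) sample.int(n, n1),
                integer(n1))
  Tm <- matrix(0L, n_draws, n)
  Tm[cbind(rep(seq_len(n_draws), each = n1), as.vector(idx))] <- 1L
  Delta <- Tm %*% data$X * (1 / n1 + 1 / n0)
  Delta <- sweep(Delta, 2, colSums(data$X) / n0, "-")
  D <- n1 * n0 / n * rowSums((Delta %*% data$cov_inv) * Delta)
  list(T = Tm, D = as.numeric(D), Delta = Delta)
}

#' Rerandomize: a pool of accepted allocations
#'
#' Accept/reject sampling of complete-randomization allocations: a draw is
#' kept when its Mahalanobis distance is at most the chi-squared threshold
#' for `p_a`. Sampling continues until `n_accept` allocations are
#' accepted; the expected number of raw draws is `n_accept / p_a`.
#'
#' @param data A [qrer_data] object.
#' @param p_a Acceptance probability in (0, 1].
#' @param n_accept Number of accepted allocations to return.
#' @param accept_floor Abort if the empirical acceptance rate over an
#'   initial probe falls below this floor (guards against an endless
#'   accept/reject loop when `p_a` is tiny relative to the covariate
#'   geometry).
#' @return An object of class `qrer_pool`: accepted allocation matrix `T`
#'   (rows are allocations, canonical unit order), their distances `D` and
#'   mean-difference vectors `Delta`, the threshold `a`, and the realized
#'   acceptance rate.
#' @examples
#' d <- simulate_qrer_study(scenario = 1, r = 1, seed = 1)
#' qd <- qrer_data(d, treated, covariates = paste0("x", 1:8), standardize = TRUE)
#' pool <- rerandomize(qd, p_a = 0.5, n_accept = 50)
#' pool
#' @export
rerandomize <- function(data, p_a = 0.1, n_accept = 1000,
                        accept_floor = 1e-4) {
  stopifnot(inherits(data, "qrer_data"))
  a <- chi2_threshold(ncol(data$X), p_a)
  chunk <- max(1024L, ceiling(min(n_accept / p_a / 4, 20000)))
  T_acc <- vector("list", 0)
  D_acc <- numeric(0)
  Delta_acc <- vector("list", 0)
  raw <- 0L
  kept <- 0L
  probe_raw <- ceiling(max(2000, 20 / p_a))
  repeat {
    b <- cr_allocation_batch(data, chunk)
    keep <- b$D <= a
    raw <- raw + chunk
    if (any(keep)) {
      T_acc[[length(T_acc) + 1]] <- b$T[keep, , drop = FALSE]
      Delta_acc[[length(Delta_acc) + 1]] <- b$Delta[keep, , drop = FALSE]
      D_acc <- c(D_acc, b$D[keep])
      kept <- kept + sum(keep)
    }
    if (raw >= probe_raw && kept / raw < accept_floor) {
      abort(paste0("acceptance rate ", signif(kept / raw, 2),
                   " below floor ", accept_floor,
                   " after ", raw, " draws; increase `p_a`"))
    }
    if (kept >= n_accept) break
  }
  Tm <- do.call(rbind, T_acc)[seq_len(n_accept), , drop = FALSE]
  Delta <- do.call(rbind, Delta_acc)[seq_len(n_accept), , drop = FALSE]
  structure(
    list(
      T = Tm, D = D_acc[seq_len(n_accept)], Delta = Delta,
      a = a, p_a = p_a, n_raw = raw,
      acceptance_rate = kept / raw
    ),
    class = "qrer_pool"
  )
}

#' @export
print.qrer_pool <- function(x, ...) {
  cat("<qrer_pool> ", nrow(x$T), " accepted allocations (p_a = ", x$p_a,
      ", a = ", signif(x$a, 5), ")\n", sep = "")
  cat("  acceptance rate ", signif(x$acceptance_rate, 3),
      "; D in [", signif(min(x$D), 3), ", ", signif(max(x$D), 3), "]\n",
      sep = "")
  invisible(x)
}

#' @describeIn rerandomize Tidy one-row-per-allocation summary of a pool.
#' @param x A `qrer_pool`.
#' @param ... Unused.
#' @method tidy qrer_pool
#' @export
tidy.qrer_pool <- function(x, ...) {
  tibble::tibble(alloc_id = seq_along(x$D), D = x$D)
}
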