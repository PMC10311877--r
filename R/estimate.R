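#' Weighted difference-in-means treatment effect
#'
#' `sum_i w_i T_i Y_i - sum_i w_i (1 - T_i) Y_i` for a weight vector
#' whose treated and control blocks each sum to one. With uniform weights
#' this is the raw difference of arm means; adding a constant to all
#' outcomes leaves it unchanged.
#'
#' @param weights Numeric weight vector aligned to `treatment`.
#' @param treatment Binary 0/1 vector.
#' @param outcome Numeric outcome vector.
#' @return A single number.
#' @examples
#' tau_hat(c(0.25, 0.75, 0.5, 0.5), c(1, 1, 0, 0), c(3, 5, 1, 1))  # 3.5
#' @export
tau_hat <- function(weights, treatment, outcome) {
  if (length(weights) != length(treatment) ||
      length(outcome) != length(treatment)) {
    abort("`weights`, `treatment` and `outcome` must have equal length")
  }
  if (anyNA(outcome)) abort("missing outcomes are not supported")
  sum(weights * treatment * outcome) - sum(weights * (1 - treatment) * outcome)
}

#' Ensembled weighted treatment effect
#'
#' The mean of the single-vector estimates over a set of weight vectors,
#' identically equal to the single-vector estimate applied to the
#' averaged weight vector (the estimator is linear in the weights).
#'
#' @param weight_matrix Matrix with one weight vector per row.
#' @inheritParams tau_hat
#' @return A single number.
#' @export
tau_ensemble <- function(weight_matrix, treatment, outcome) {
  if (is.null(dim(weight_matrix))) weight_matrix <- matrix(weight_matrix, nrow = 1)
  if (nrow(weight_matrix) < 1) abort("at least one weight vector is required")
  tau_hat(colMeans(weight_matrix), treatment, outcome)
}

#' Weighted linear-model inference for the population effect
#'
#' Fits intercept + treatment by weighted least squares with case weights
#' `(n1 T_i + n0 (1 - T_i)) w_i` (so uniform weights reduce to OLS); the
#' point estimate equals the weighted difference in means exactly, and
#' the standard error comes from a heteroskedasticity-robust sandwich
#' with normal-quantile confidence limits.
#'
#' @inheritParams tau_hat
#' @param level Confidence level.
#' @param vcov_type Sandwich flavor passed to [sandwich::vcovHC]
#'   (`"HC0"`-`"HC3"`; default the degrees-of-freedom-corrected `"HC1"`).
#' @return A one-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `level`.
#' @export
pate_inference <- function(weights, treatment, outcome, level = 0.95,
                           vcov_type = "HC1") {
  if (length(weights) != length(treatment) ||
      length(outcome) != length(treatment)) {
    abort("`weights`, `treatment` and `outcome` must have equal length")
  }
  n1 <- sum(treatment)
  n0 <- sum(1 - treatment)
  cw <- (n1 * treatment + n0 * (1 - treatment)) * weights
  if (sum(cw[treatment == 1] > 0) < 2 || sum(cw[treatment == 0] > 0) < 2) {
    abort("robust variance undefined: fewer than two units with positive weight in an arm")
  }
  fit <- lm(outcome ~ treatment, weights = cw)
  est <- unname(coef(fit)["treatment"])
  se <- sqrt(sandwich::vcovHC(fit, type = vcov_type)["treatment", "treatment"])
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    estimate = est, std.error = se,
    conf.low = est - z * se, conf.high = est + z * se,
    level = level
  )
}

#' Rerandomized-experiment estimate
#'
#' Draws one accepted allocation, obtains responses under it, and returns
#' the unweighted difference in arm means -- the estimator a rerandomized
#' experiment would use. In simulation mode `response_fn` regenerates the
#' responses for a candidate allocation; in design mode pass the observed
#' outcomes recorded under the accepted allocation.
#'
#' @param data A [qrer_data] object.
#' @param p_a Acceptance probability.
#' @param response_fn Function taking a binary allocation vector (in the
#'   original row order of the data) and returning the outcome vector.
#' @return A list: `estimate`, the allocation `t` (original order) and
#'   its distance `d`.
#' @export
rer_estimate <- function(data, p_a, response_fn) {
  stopifnot(inherits(data, "qrer_data"), is.function(response_fn))
  pool <- rerandomize(data, p_a, 1)
  t_canon <- as.integer(pool$T[1, ])
  inv <- order(data$perm)
  t_orig <- t_canon[inv]
  y <- response_fn(t_orig)
  if (length(y) != data$n) abort("`response_fn` must return one outcome per unit")
  list(
    estimate = mean(y[t_orig == 1]) - mean(y[t_orig == 0]),
    t = t_orig,
    d = pool$D[1]
  )
}
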