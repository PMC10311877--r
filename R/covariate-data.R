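#' Assemble unit-level data for rerandomization and reweighting
#'
#' Builds the internal covariate container used by all balancing routines:
#' a numeric covariate matrix together with the observed binary treatment
#' allocation. Units are internally permuted so that treated units come
#' first (the canonical ordering used by the weight generator); the
#' permutation is stored and inverted whenever per-unit results are
#' returned.
#'
#' @param data A data frame with one row per unit.
#' @param treatment Column (bare name or string) holding the binary
#'   treatment indicator; values must be exactly 0/1 (or logical).
#' @param covariates Character vector of covariate column names. Defaults
#'   to all numeric columns other than the treatment.
#' @param standardize If `TRUE`, columns are centred and scaled to unit
#'   variance (sample, n-1 denominator). The Mahalanobis distance is
#'   invariant to this, but the kernel loss and regularizers are not, so
#'   standardizing puts covariates on a common scale.
#' @param ridge Optional nonnegative ridge `eps` added as `eps * I` to the
#'   sample covariance before inversion. Default 0: a singular covariance
#'   is an error, never silently pseudo-inverted.
#'
#' @return An object of class `qrer_data`: a list with the covariate
#'   matrix `X` (canonical order), group sizes `n1`/`n0`, the canonical
#'   treatment vector, the stored permutation and the inverse covariance
#'   used by Mahalanobis distances.
#' @examples
#' d <- simulate_qrer_study(scenario = 1, r = 1, seed = 1)
#' qd <- qrer_data(d, treatment = treated)
#' qd
#' @export
qrer_data <- function(data, treatment, covariates = NULL,
                      standardize = FALSE, ridge = 0) {
  stopifnot(is.data.frame(data))
  tq <- rlang::enquo(treatment)
  tname <- rlang::as_name(tq)
  if (!tname %in% names(data)) {
    abort(paste0("treatment column '", tname, "' not found in `data`"))
  }
  t_raw <- data[[tname]]
  if (is.logical(t_raw)) t_raw <- as.integer(t_raw)
  if (!all(t_raw %in% c(0, 1))) {
    abort("treatment column must be binary 0/1")
  }
  t_raw <- as.integer(t_raw)

  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          tname)
  }
  if (length(covariates) < 1) abort("at least one covariate is required")
  X <- as.matrix(data[, covariates, drop = FALSE])
  if (!is.numeric(X)) abort("covariates must be numeric")
  if (anyNA(X) || anyNA(t_raw)) abort("missing values are not supported")

  n <- nrow(X)
  n1 <- sum(t_raw)
  n0 <- n - n1
  if (n1 < 2 || n0 < 2) {
    abort("need at least 2 treated and 2 control units (covariance must be estimable in each arm)")
  }

  if (standardize) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      abort(paste0("cannot standardize constant column(s): ",
                   paste(covariates[sds == 0], collapse = ", ")))
    }
    X <- scale(X)[, , drop = FALSE]
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }

  # canonical ordering: treated block first, controls after
  perm <- order(1L - t_raw)  # stable: preserves within-arm order
  Xc <- X[perm, , drop = FALSE]
  t_canon <- t_raw[perm]

  S <- stats::cov(Xc)
  if (ridge > 0) S <- S + diag(ridge, ncol(S))
  qr_S <- qr(S)
  if (qr_S$rank < ncol(S)) {
    abort(paste0("sample covariance of the covariates is singular (rank ",
                 qr_S$rank, " < ", ncol(S),
                 "); drop collinear columns or supply `ridge` > 0"))
  }
  S_inv <- chol2inv(chol(S))

  structure(
    list(
      X = Xc, n = n, n1 = n1, n0 = n0,
      t_obs = t_canon,
      covariates = covariates,
      perm = perm,
      unit_id = if (!is.null(rownames(data))) rownames(data)[perm] else as.character(perm),
      cov_inv = S_inv,
      standardized = standardize,
      ridge = ridge
    ),
    class = "qrer_data"
  )
}

#' @export
print.qrer_data <- function(x, ...) {
  cat("<qrer_data> ", x$n, " units (", x$n1, " treated, ", x$n0,
      " control), ", ncol(x$X), " covariates\n", sep = "")
  cat("  covariates: ", paste(head(x$covariates, 8), collapse = ", "),
      if (length(x$covariates) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# split the canonical covariate matrix into arm blocks
arm_blocks <- function(data) {
  list(
    X1 = data$X[seq_len(data$n1), , drop = FALSE],
    X0 = data$X[data$n1 + seq_len(data$n0), , drop = FALSE]
  )
}
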