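test_that("Mahalanobis distance matches hand evaluation and brute force on the 4-point instance", {
  qd <- tiny_data()
  # treated mean 1.5, control mean 3.5, cov 5/3: (2*2/4) * 4 / (5/3) = 2.4
  expect_equal(mahalanobis_distance(qd), 2.4, tolerance = 1e-12)
  # symmetric split balances the means exactly
  expect_equal(mahalanobis_distance(qd, c(0, 1, 1, 0)), 0, tolerance = 1e-12)
  # every enumerable allocation agrees with the brute-force transcription
  X <- qd$X
  allocs <- enumerate_allocations(4, 2)
  for (i in seq_len(nrow(allocs))) {
    expect_equal(mahalanobis_distance(qd, allocs[i, ]),
                 mahalanobis_bf(X, allocs[i, ]), tolerance = 1e-10)
  }
})

test_that("distance agrees with brute force for every allocation of a larger instance", {
  set.seed(41)
  qd <- random_data(n1 = 4, n0 = 4, d = 3)
  allocs <- enumerate_allocations(8, 4)
  ours <- apply(allocs, 1, function(t) mahalanobis_distance(qd, t))
  bf <- apply(allocs, 1, function(t) mahalanobis_bf(qd$X, t))
  expect_equal(ours, bf, tolerance = 1e-10)
})

test_that("distance is invariant under invertible affine maps of the covariates", {
  set.seed(42)
  for (i in 1:5) {
    n1 <- 5; n0 <- 7; d <- 3
    X <- matrix(rnorm((n1 + n0) * d), n1 + n0, d)
    repeat {
      A <- matrix(rnorm(d * d), d, d)
      if (abs(det(A)) > 0.1) break
    }
    b <- rnorm(d)
    t <- sample(c(rep(1, n1), rep(0, n0)))
    mk <- function(M) {
      df <- as.data.frame(M); names(df) <- paste0("x", 1:d); df$treated <- t
      qrer_data(df, treated)
    }
    d1 <- mahalanobis_distance(mk(X), mk(X)$t_obs)
    d2 <- mahalanobis_distance(mk(sweep(X %*% A, 2, b, "+")),
                               mk(X)$t_obs)
    expect_lt(abs(d1 - d2), 1e-8)
  }
})

test_that("chi-squared threshold solves P(chi2_d <= a) = p_a", {
  # frozen independent oracle values (scipy.stats.chi2.ppf)
  expect_equal(chi2_threshold(8, 0.1), 3.4895391256498227, tolerance = 1e-9)
  expect_equal(chi2_threshold(8, 0.5), 7.344121497701794, tolerance = 1e-9)
  expect_identical(chi2_threshold(8, 1), Inf)
  expect_lt(chi2_threshold(1, 1e-10), 1e-6)
  expect_error(chi2_threshold(8, 0), "p_a")
  expect_error(chi2_threshold(8, 1.2), "p_a")
})

test_that("complete-randomization sampling is uniform over the constrained set", {
  set.seed(7)
  d <- data.frame(x = rnorm(4), treated = c(1, 1, 0, 0))
  qd <- qrer_data(d, treated)
  n_draws <- 60000
  keys <- character(n_draws)
  sums <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    a <- sample_cr_allocation(qd)
    sums[i] <- sum(a$t)
    keys[i] <- paste(a$t, collapse = "")
  }
  expect_true(all(sums == 2))  # exact group-size constraint
  counts <- table(keys)
  expect_length(counts, 6)
  chi <- sum((counts - n_draws / 6)^2 / (n_draws / 6))
  # chi-square GOF with 5 df; 0.999 quantile ~ 20.5
  expect_lt(chi, 20.5)
})

test_that("mean CR distance approximates the covariate dimension", {
  set.seed(8)
  n <- 500
  df <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(df) <- paste0("x", 1:8)
  df$treated <- c(rep(1, 250), rep(0, 250))
  qd <- qrer_data(df, treated)
  b <- qrer:::cr_allocation_batch(qd, 10000)
  se <- sd(b$D) / sqrt(length(b$D))
  expect_lt(abs(mean(b$D) - 8), 3 * se)
})

test_that("rerandomized pools respect the threshold and calibrated acceptance rate", {
  set.seed(9)
  n <- 500
  df <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(df) <- paste0("x", 1:8)
  df$treated <- c(rep(1, 250), rep(0, 250))
  qd <- qrer_data(df, treated)

  pool <- rerandomize(qd, p_a = 1, n_accept = 100)
  expect_equal(nrow(pool$T), 100)
  expect_equal(pool$acceptance_rate, 1)

  pool <- rerandomize(qd, p_a = 0.1, n_accept = 500)
  expect_true(all(pool$D <= pool$a))
  expect_true(all(rowSums(pool$T) == 250))
  # acceptance fraction close to p_a (binomial 3-sigma on the raw draws)
  tol <- 3 * sqrt(0.1 * 0.9 / pool$n_raw)
  expect_lt(abs(pool$acceptance_rate - 0.1), tol + 0.005)

  td <- tidy(pool)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 500)
})

test_that("degenerate inputs are rejected with informative errors", {
  df <- data.frame(x1 = 1:6, x2 = (1:6) * 2, treated = rep(c(1, 0), 3))
  expect_error(qrer_data(df, treated), "singular")
  expect_error(qrer_data(data.frame(x = 1:3, treated = c(1, 0, 0)), treated),
               "at least 2")
  expect_error(qrer_data(data.frame(x = 1:4, treated = c(2, 1, 0, 0)), treated),
               "binary")
  # ridge rescues exact collinearity explicitly
  qd <- qrer_data(df, treated, ridge = 1e-6)
  expect_true(is.finite(mahalanobis_distance(qd)))
})
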