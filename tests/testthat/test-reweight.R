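test_that("Dirichlet weight draws sit on the arm simplices with flat-Dirichlet moments", {
  set.seed(11)
  W <- sample_dirichlet_weights(3, 4, n_draws = 50000)
  expect_true(all(W >= 0))
  expect_equal(rowSums(W[, 1:3]), rep(1, 50000), tolerance = 1e-12)
  expect_equal(rowSums(W[, 4:7]), rep(1, 50000), tolerance = 1e-12)
  # flat Dir(1,1,1): mean 1/3, variance 2 / (9 * 4) = 1/18
  mc_tol_mean <- 3 * sqrt(1 / 18 / 50000)
  expect_true(all(abs(colMeans(W[, 1:3]) - 1 / 3) < mc_tol_mean))
  expect_true(all(abs(apply(W[, 1:3], 2, var) - 1 / 18) < 0.005))
  # degenerate one-unit simplex
  expect_equal(as.vector(sample_dirichlet_weights(1, 2)[, 1]), 1)
})

test_that("weighted mean difference matches hand arithmetic and reduces to arm means", {
  qd <- tiny_data()
  expect_equal(unname(weighted_mean_difference(qd, c(0.25, 0.75, 0.5, 0.5))),
               -1.75, tolerance = 1e-12)
  # uniform weights reduce to the plain difference of arm means
  expect_equal(unname(weighted_mean_difference(qd, rep(0.5, 4))),
               1.5 - 3.5, tolerance = 1e-12)
  # point masses pick out single units
  expect_equal(unname(weighted_mean_difference(qd, c(1, 0, 0, 1))),
               1 - 4, tolerance = 1e-12)
  expect_error(weighted_mean_difference(qd, rep(0.5, 5)), "length")
  expect_error(weighted_mean_difference(qd, c(0.3, 0.3, 0.5, 0.5)), "sum to 1")
})

test_that("weighted mean difference is linear in the weights", {
  set.seed(12)
  qd <- random_data()
  wa <- sample_dirichlet_weights(qd$n1, qd$n0)
  wb <- sample_dirichlet_weights(qd$n1, qd$n0)
  for (alpha in c(0, 0.3, 0.7, 1)) {
    lhs <- weighted_mean_difference(qd, drop(alpha * wa + (1 - alpha) * wb))
    rhs <- alpha * weighted_mean_difference(qd, drop(wa)) +
      (1 - alpha) * weighted_mean_difference(qd, drop(wb))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("weighted Mahalanobis reduces to the allocation distance under uniform weights", {
  qd <- tiny_data()
  res <- weighted_mahalanobis(qd, rep(0.5, 4))
  expect_equal(res$d_w, 2.4, tolerance = 1e-10)
  expect_equal(sum(res$w_star), 1, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:5) {
    qd <- random_data(n1 = 5, n0 = 9, d = 3)
    w_unif <- c(rep(1 / 5, 5), rep(1 / 9, 9))
    expect_equal(weighted_mahalanobis(qd, w_unif)$d_w,
                 mahalanobis_distance(qd),
                 tolerance = 1e-8)
  }
})

test_that("weighted Mahalanobis equals the term-by-term transcription on random weights", {
  set.seed(14)
  for (i in 1:5) {
    qd <- random_data(n1 = 3, n0 = 3, d = 2)
    w <- drop(sample_dirichlet_weights(3, 3))
    expect_equal(weighted_mahalanobis(qd, w)$d_w,
                 weighted_mahalanobis_bf(qd$X, qd$t_obs, w),
                 tolerance = 1e-8)
  }
})

test_that("weighted distance is nonnegative and zero iff the delta vanishes", {
  set.seed(15)
  qd <- random_data()
  W <- sample_dirichlet_weights(qd$n1, qd$n0, 50)
  dw <- weighted_mahalanobis(qd, W)
  expect_true(all(dw >= 0))
  # degenerate all-mass-on-one-unit weights are rejected
  w_deg <- c(1, rep(0, qd$n1 - 1), 1, rep(0, qd$n0 - 1))
  expect_error(weighted_mahalanobis(qd, w_deg), "degenerate|singular")
})

test_that("weights round-trip to the original unit order", {
  set.seed(16)
  df <- data.frame(x1 = rnorm(8), x2 = rnorm(8),
                   treated = c(0, 1, 0, 1, 1, 0, 0, 1))
  qd <- qrer_data(df, treated)
  w <- drop(sample_dirichlet_weights(4, 4))
  tb <- weights_tibble(qd, w)
  expect_equal(tb$treated, df$treated)
  # treated weights sum to one after the inverse permutation too
  expect_equal(sum(tb$weight[tb$treated == 1]), 1, tolerance = 1e-12)
  expect_equal(sum(tb$weight[tb$treated == 0]), 1, tolerance = 1e-12)
})
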