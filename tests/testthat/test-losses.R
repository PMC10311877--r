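test_that("RBF kernel has the closed form and its limits", {
  expect_equal(rbf_kernel(c(0, 0), c(0, 0), 1), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 5), 1)
  expect_gt(rbf_kernel(0, 10, 1e-8), 0.999)  # gamma -> 0 sends K -> 1
  expect_error(rbf_kernel(0, 1, 0), "gamma")
  expect_error(rbf_kernel(c(0, 1), 1, 1), "length")
})

test_that("MMD matches hand value, vanishes on identical samples, and equals the double-loop oracle", {
  # B = 1 hand value: sqrt(1 + 1 - 2 exp(-1))
  expect_equal(mmd_loss(matrix(0), matrix(1), 1),
               sqrt(2 - 2 * exp(-1)), tolerance = 1e-12)
  set.seed(21)
  A <- matrix(rnorm(40), 20, 2)
  expect_equal(mmd_loss(A, A, 0.7), 0, tolerance = 1e-12)
  for (B in c(3, 17, 64)) {
    X <- matrix(rnorm(B * 3), B, 3)
    Y <- matrix(rnorm(B * 3, sd = 1.4), B, 3)
    g <- runif(1, 0.2, 2)
    expect_equal(mmd_loss(X, Y, g), mmd_bf(X, Y, g), tolerance = 1e-10)
  }
  expect_error(mmd_loss(matrix(rnorm(4), 2), matrix(rnorm(6), 3), 1),
               "identical dimensions")
})

test_that("single-precision training-path MMD agrees with the reference computation", {
  set.seed(22)
  qd <- small_sim_data(20, 20, 3)
  model <- build_generator(20, 20, hidden = 64)
  ab <- qrer:::arm_blocks(qd)
  Wb <- sample_dirichlet_weights(20, 20, 32)
  dT <- matrix(rnorm(32 * 3, sd = 0.1), 32, 3)
  ones <- matrix(1, 32, 64)
  gamma <- 2.5
  qrer:::net_set_log_gamma(qrer:::generator_ptr(model), log(gamma))
  res <- qrer:::net_train_step(qrer:::generator_ptr(model), Wb, ones, ones,
                               dT, ab$X1, ab$X0, colMeans(qd$X), 1, 1, FALSE)
  # recompute the three loss terms in double precision on the pre-update
  # outputs: the theta step already happened, so rebuild the same forward
  # pass from the stored pre-step parameters is not possible; instead
  # check the magnitudes are consistent with the R losses on a fresh
  # forward pass of the *updated* network (one Adam step moves the loss
  # only slightly)
  Wt <- forward_generator(model, Wb, dropout_active = FALSE)
  mmd_r <- mmd_loss(weighted_mean_difference(qd, Wt), dT, gamma)
  expect_lt(abs(res[1] - mmd_r), 0.05)
  expect_equal(res[2], regularizer_balance(qd, Wt), tolerance = 0.05)
})

test_that("balance regularizer matches hand arithmetic and its zero condition", {
  qd <- tiny_data()
  # uniform weights: arm means 1.5 and 3.5 against pooled mean 2.5
  expect_equal(regularizer_balance(qd, rep(0.5, 4)), 2.0, tolerance = 1e-12)
  # weights reproducing the pooled mean in both arms make it vanish:
  # arm means hit 2.5 with w1 = (0, 1) * ... solve: 1*a + 2*(1-a) = 2.5
  # impossible on [1,2]; use a 3-unit arm instance instead
  df <- data.frame(x = c(1, 4, 2, 3), treated = c(1, 1, 0, 0))
  qd2 <- qrer_data(df, treated)
  w <- c(0.5, 0.5, 0.5, 0.5)  # arm means (1+4)/2 = 2.5 = (2+3)/2 = pooled
  expect_equal(regularizer_balance(qd2, w), 0, tolerance = 1e-12)
  set.seed(23)
  qd3 <- random_data(5, 5, 2)
  W <- sample_dirichlet_weights(5, 5, 7)
  expect_equal(regularizer_balance(qd3, W),
               reg_balance_bf(qd3$X, qd3$t_obs, W), tolerance = 1e-12)
})

test_that("dispersion regularizer matches hand arithmetic and vanishes only at uniform", {
  expect_equal(regularizer_dispersion(c(1, 0, 0.5, 0.5), 2, 2), 0.5,
               tolerance = 1e-12)
  expect_equal(regularizer_dispersion(c(0.5, 0.5, 0.5, 0.5), 2, 2), 0,
               tolerance = 1e-12)
  set.seed(24)
  W <- sample_dirichlet_weights(4, 3, 6)
  expect_equal(regularizer_dispersion(W, 4, 3),
               reg_dispersion_bf(W, 4, 3), tolerance = 1e-12)
  expect_gt(regularizer_dispersion(W, 4, 3), 0)
})

test_that("total objective is the sum of its three parts", {
  set.seed(25)
  qd <- random_data(5, 6, 2)
  W <- sample_dirichlet_weights(5, 6, 10)
  dT <- matrix(rnorm(20), 10, 2)
  g <- 0.8
  expect_equal(total_loss(qd, W, dT, g, lambda1 = 1.3, lambda2 = 0.7),
               mmd_loss(weighted_mean_difference(qd, W), dT, g) +
                 1.3 * regularizer_balance(qd, W) +
                 0.7 * regularizer_dispersion(W, 5, 6),
               tolerance = 1e-12)
  # lambda1 = lambda2 = 0 leaves the bare MMD
  expect_equal(total_loss(qd, W, dT, g, 0, 0),
               mmd_loss(weighted_mean_difference(qd, W), dT, g),
               tolerance = 1e-12)
})

test_that("KS statistic matches enumerated empirical CDF values", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(3, 4)), 1)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  expect_error(ks_statistic(numeric(0), 1), "nonempty")
})
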