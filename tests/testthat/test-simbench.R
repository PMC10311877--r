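test_that("design standardized mean differences round to the intended 0.2 and 0.5", {
  for (sc in 1:3) {
    smd <- design_smd(sc)$smd
    expect_equal(round(smd, 1), c(0.2, 0.2, 0.5, 0.5, 0.2, 0.2, 0.5, 0.5))
  }
  # Bernoulli hand values
  smd <- design_smd(1)$smd
  expect_equal(smd[5], 0.068 / sqrt((0.168 * 0.832 + 0.1 * 0.9) / 2),
               tolerance = 1e-12)
  expect_equal(smd[7], 0.242 / sqrt((0.642 * 0.358 + 0.4 * 0.6) / 2),
               tolerance = 1e-12)
})

test_that("simulated covariates reproduce the scenario moments empirically", {
  set.seed(71)
  # pool many replicates for a large-sample check of scenario 2's x3
  xs_t <- c(); xs_c <- c()
  for (i in 1:40) {
    d <- simulate_qrer_study(scenario = 2, r = 1)
    xs_t <- c(xs_t, d$x3[d$treated == 1])
    xs_c <- c(xs_c, d$x3[d$treated == 0])
  }
  # treated: N(sqrt(1.5)*0.5, 2); control: N(0, 1)
  expect_lt(abs(mean(xs_t) - sqrt(1.5) * 0.5), 3 * sqrt(2 / length(xs_t)))
  expect_lt(abs(var(xs_t) - 2), 0.1)
  expect_lt(abs(mean(xs_c)), 3 * sqrt(1 / length(xs_c)))
  emp_smd <- (mean(xs_t) - mean(xs_c)) / sqrt((var(xs_t) + var(xs_c)) / 2)
  expect_lt(abs(emp_smd - 0.5), 0.03)
})

test_that("response surfaces match hand evaluation on a crafted unit", {
  # unit with x1 = x3 = x5 = x7 = 1, control, no noise
  X <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 1, 8)
  expect_equal(qrer:::g_surface(X, "linear"), 12.0)
  expect_equal(qrer:::g_surface(X, "interaction"), 17.0)
  expect_equal(qrer:::g_surface(X, "polynomial"), 18.0)
})

test_that("datasets carry standardized copies, correct sizes, and valid responses", {
  d <- simulate_qrer_study(scenario = 1, r = 2, seed = 72)
  expect_equal(nrow(d), 750)
  expect_equal(sum(d$treated), 250)
  for (j in paste0("x", 1:8)) {
    expect_lt(abs(mean(d[[paste0(j, "_std")]])), 1e-8)
    expect_lt(abs(var(d[[paste0(j, "_std")]]) - 1), 1e-8)
  }
  # responses recompute from the raw covariates given the shared noise
  eps <- d$y_linear - qrer:::g_surface(as.matrix(d[, paste0("x", 1:8)]), "linear") -
    d$treated
  expect_equal(d$y_interaction,
               qrer:::g_surface(as.matrix(d[, paste0("x", 1:8)]), "interaction") +
                 d$treated + eps, tolerance = 1e-10)
  expect_error(standardize_covariates(data.frame(a = rep(1, 5)), "a"),
               "constant")
})

test_that("the r = 1 dataset is a bit-identical row subset of the paired r = 2 dataset", {
  d2 <- simulate_qrer_study(scenario = 3, r = 2, seed = 73)
  d1 <- simulate_qrer_study(scenario = 3, r = 1, seed = 73)
  shared <- c(paste0("x", 1:8), "treated", "y_linear", "y_interaction",
              "y_polynomial")
  for (cl in shared) {
    expect_identical(d1[[cl]], d2[[cl]][seq_len(500)])
  }
})

test_that("Mahalanobis distance is unchanged by standardization of the covariates", {
  d <- simulate_qrer_study(scenario = 1, r = 1, seed = 74)
  qd_raw <- qrer_data(d, treated, covariates = paste0("x", 1:8))
  qd_std <- qrer_data(d, treated, covariates = paste0("x", 1:8),
                      standardize = TRUE)
  expect_equal(mahalanobis_distance(qd_raw), mahalanobis_distance(qd_std),
               tolerance = 1e-8)
})

test_that("benchmark runs are deterministic given a seed and aggregate correctly", {
  set.seed(75)
  r1 <- run_rer_benchmark(1, 1, "linear", p_a = 1, n_reps = 4)
  set.seed(75)
  r2 <- run_rer_benchmark(1, 1, "linear", p_a = 1, n_reps = 4)
  expect_identical(r1, r2)
  s <- summarize_benchmark(r1)
  expect_equal(s$n_reps, 4)
  expect_gte(s$rmse, abs(s$bias))
  # exact replicates: zero error implies zero bias and rmse
  fake <- r1 |> dplyr::mutate(error = 0, estimate = 1)
  sf <- summarize_benchmark(fake)
  expect_equal(sf$bias, 0)
  expect_equal(sf$rmse, 0)
})

test_that("balance comparison returns valid KS statistics and p-values per covariate", {
  qd <- small_sim_data(seed = 76)
  set.seed(76)
  model <- train_qrer(qd, small_train_config())
  model$train_state$p_a <- 0.5
  bal <- balance_comparison(model, n_vectors = 200, data = qd)
  expect_equal(nrow(bal), 4)
  expect_true(all(bal$ks_statistic >= 0 & bal$ks_statistic <= 1))
  expect_true(all(bal$p_value >= 0 & bal$p_value <= 1))
  # a delta sample against itself: KS 0, p-value 1
  expect_equal(ks_statistic(bal$ks_statistic, bal$ks_statistic), 0)
})
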