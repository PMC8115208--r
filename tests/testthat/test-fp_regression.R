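test_that("demean: arithmetic, constants, idempotence", {
  expect_equal(demean(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(demean(rep(4.2, 7)), rep(0, 7))
  x <- rnorm(31)
  expect_equal(demean(demean(x)), demean(x))
  expect_lt(abs(mean(demean(x))), 1e-12)
})

test_that("exact linear relation gives the exact coefficients and R2 = 1", {
  com_x <- c(-2, -1, 0, 1, 2) * 0.01
  com_v <- c(1, -1, 0, -1, 1) * 0.1
  fp <- 2 * com_x
  pt <- fit_point(com_x, com_v, fp)
  expect_equal(pt$beta1, 2, tolerance = 1e-12)
  expect_equal(pt$beta2, 0, tolerance = 1e-12)
  expect_equal(pt$r2, 1, tolerance = 1e-12)
})

test_that("worked 5-step example matches the normal-equations oracle", {
  com_x <- c(-2, -1, 0, 1, 2) * 0.01
  com_v <- c(1, -1, 0, -1, 1) * 0.1
  eps <- c(0.003, -0.001, 0.002, -0.002, -0.002)
  fp <- 0.9 * com_x + 0.12 * com_v + eps
  pt <- fit_point(com_x, com_v, fp)
  X <- cbind(com_x - mean(com_x), com_v - mean(com_v))
  y <- fp - mean(fp)
  beta <- pinv_lsq(X, y)
  expect_equal(pt$beta1, beta[1], tolerance = 1e-10)
  expect_equal(pt$beta2, beta[2], tolerance = 1e-10)
  rss <- sum((y - X %*% beta)^2)
  expect_equal(pt$r2, 1 - rss / sum(y^2), tolerance = 1e-10)
})

test_that("fit_point agrees with a pseudo-inverse solve on random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    com_x <- rnorm(n, sd = 0.02)
    com_v <- rnorm(n, sd = 0.1)
    fp <- 0.12 + rnorm(1) * com_x + rnorm(1) * com_v + rnorm(n, sd = 0.01)
    pt <- fit_point(com_x, com_v, fp)
    X <- cbind(demean(com_x), demean(com_v))
    beta <- pinv_lsq(X, demean(fp))
    expect_equal(c(pt$beta1, pt$beta2), beta, tolerance = 1e-10)
  }
})

test_that("null predictors give r2 near 2/(n-1) on average", {
  set.seed(7)
  n <- 50
  r2s <- replicate(400, {
    fit_point(rnorm(n), rnorm(n), rnorm(n))$r2
  })
  # under the null, E[R2] = p/(n-1) with p = 2 predictors
  expect_equal(mean(r2s), 2 / (n - 1), tolerance = 0.25)
})

test_that("internal consistency: r2 = 1 - resid_var * n / TSS", {
  set.seed(8)
  com_x <- rnorm(30); com_v <- rnorm(30)
  fp <- 0.5 * com_x - 0.2 * com_v + rnorm(30)
  pt <- fit_point(com_x, com_v, fp)
  tss <- sum(demean(fp)^2)
  expect_equal(pt$r2, 1 - pt$resid_var * pt$n_steps / tss, tolerance = 1e-10)
})

test_that("R2 is invariant to unit rescaling and affine shifts", {
  set.seed(9)
  com_x <- rnorm(40, 0.05, 0.01)
  com_v <- rnorm(40, 0.1, 0.05)
  fp <- 0.8 * com_x + 0.3 * com_v + rnorm(40, sd = 0.005)
  base <- fit_point(com_x, com_v, fp)
  mm <- fit_point(com_x * 1000, com_v * 1000, fp)      # mm predictors
  shifted <- fit_point(com_x + 3, com_v - 2, fp + 10)  # constant offsets
  expect_equal(mm$r2, base$r2, tolerance = 1e-12)
  expect_equal(mm$beta1 * 1000, base$beta1, tolerance = 1e-9)
  expect_equal(shifted$r2, base$r2, tolerance = 1e-10)
})

test_that("collinear predictors are flagged missing, not zero", {
  x <- rnorm(20)
  pt <- fit_point(x, 2 * x, 0.5 * x + rnorm(20, sd = 0.01))
  expect_true(is.na(pt$r2))
  expect_true(is.na(pt$beta1))
})

test_that("mid-grid estimates are unbiased over replicate synthetic cells", {
  set.seed(10)
  b1 <- 0.9; b2 <- 0.12
  n <- 40
  est <- t(replicate(200, {
    com_x <- rnorm(n, sd = 0.015)
    com_v <- rnorm(n, sd = 0.08)
    fp <- b1 * com_x + b2 * com_v + rnorm(n, sd = 0.008)
    pt <- fit_point(com_x, com_v, fp)
    c(pt$beta1, pt$beta2)
  }))
  se_mean <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - b1), 2 * se_mean[1])
  expect_lt(abs(mean(est[, 2]) - b2), 2 * se_mean[2])
})

test_that("fit_series fits every node on the identical step set", {
  set.seed(11)
  n_steps <- 30
  com_x <- matrix(rnorm(n_steps * 51), n_steps, 51)
  com_v <- matrix(rnorm(n_steps * 51), n_steps, 51)
  fp <- rnorm(n_steps)
  com_x[4, 20] <- NA  # one bad node drops the whole step everywhere
  ser <- fit_series(com_x, com_v, fp)
  expect_s3_class(ser, "regression_series")
  expect_equal(nrow(ser), 51)
  expect_equal(ser$node_pct, seq(0, 100, 2))
  expect_true(all(ser$n_steps == n_steps - 1))
})

test_that("fit_series skips cells with too few steps, with a warning", {
  com_x <- matrix(rnorm(5 * 51), 5, 51)
  com_v <- matrix(rnorm(5 * 51), 5, 51)
  expect_warning(out <- fit_series(com_x, com_v, rnorm(5)), "usable steps")
  expect_null(out)
})

test_that("deterministic end-of-swing placement yields r2 = 1 at contact", {
  tr <- simulate_trial(walker_config("control", seed = 15, n_steps = 60,
                                     placement_noise_sd = 0,
                                     process_noise_sd = 0,
                                     control_node_pct = 100))
  ser <- trial_series(tr)
  expect_equal(ser$r2[ser$node_pct == 100], 1, tolerance = 1e-9)
})

test_that("r2 rises across the swing with mid-swing control and noise", {
  # gains re-centered on the mid-swing dead-beat solution, with enough
  # within-step noise that early-swing state only partly predicts the
  # state the controller acts on
  tr <- simulate_trial(walker_config("control", seed = 16, n_steps = 80,
                                     control_node_pct = 50,
                                     gain_pos = 2.37, gain_vel = 0.73,
                                     process_noise_sd = 0.2,
                                     state_noise_sd = 0.02,
                                     placement_noise_sd = 0.004))
  ser <- trial_series(tr)
  upto <- ser$node_pct <= 50
  inc <- diff(ser$r2[upto])
  # monotone trend over at least 80% of consecutive node pairs up to the
  # control node, and the contact-node value exceeds the foot-off value
  expect_gte(mean(inc > 0), 0.8)
  expect_gt(ser$r2[ser$node_pct == 50], ser$r2[ser$node_pct == 0])
})
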