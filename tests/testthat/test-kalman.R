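test_that("a noiseless linear map is recovered exactly", {
  X <- matrix(seq(0.01, 1, length.out = 200))     # constant-velocity ramp
  Z <- 3 * X
  m <- fit_kalman(Z, X, ridge_lambda = 0)
  expect_equal(as.numeric(m$H), 3, tolerance = 1e-9)
  expect_lt(abs(m$Q[1, 1]), 1e-18)
})

test_that("ridge shrinks the observation matrix to zero in the limit", {
  set.seed(1)
  X <- matrix(rnorm(100))
  Z <- 2 * X + matrix(rnorm(100, 0, 0.1))
  m <- fit_kalman(Z, X, ridge_lambda = 1e12)
  expect_lt(max(abs(m$H)), 1e-6)
})

test_that("fit_kalman names the degenerate DOF", {
  X <- cbind(rnorm(50), 0, rnorm(50))
  Z <- matrix(rnorm(50 * 2), 50, 2)
  expect_error(fit_kalman(Z, X), "DOF 2")
})

test_that("state and observation parameters are recovered from simulated data", {
  # x_t = 0.9 x_{t-1} + N(0, 0.5^2), z_t = 2 x_t + N(0, 1), T = 1e5
  set.seed(20)
  T_ <- 1e5
  x <- numeric(T_)
  for (t in 2:T_) x[t] <- 0.9 * x[t - 1] + rnorm(1, 0, 0.5)
  z <- 2 * x + rnorm(T_)
  m <- fit_kalman(matrix(z), matrix(x), ridge_lambda = 0)
  expect_equal(as.numeric(m$A), 0.9, tolerance = 0.02)
  expect_equal(as.numeric(m$H), 2, tolerance = 0.05)
  expect_equal(as.numeric(m$W), 0.25, tolerance = 0.02)
  expect_equal(as.numeric(m$Q), 1, tolerance = 0.05)
})

test_that("one scalar step matches the hand-computed closed form", {
  # a = 1, w = 0.25, h = 1, q = 1, x0 = 0, P0 = 1, z = 1:
  #   P- = 1.25, K = 1.25 / 2.25, x+ = K * 1, P+ = (1 - K) * 1.25
  model <- list(A = matrix(1), W = matrix(0.25), H = matrix(1), Q = matrix(1),
                feature_mean = 0, d = 1L, p = 1L, ridge_lambda = 0)
  class(model) <- "kalman_model"
  st <- kalman_step(model, list(x = 0, P = matrix(1)), 1)
  K <- 1.25 / 2.25
  expect_equal(st$x, K, tolerance = 1e-12)
  expect_equal(st$P[1, 1], (1 - K) * 1.25, tolerance = 1e-12)
})

test_that("limiting behavior of the update is correct", {
  # H = 0: the observation carries no information
  model <- list(A = matrix(0.8), W = matrix(0.1), H = matrix(0), Q = matrix(1),
                feature_mean = 0, d = 1L, p = 1L, ridge_lambda = 0)
  class(model) <- "kalman_model"
  st <- kalman_step(model, list(x = 2, P = matrix(0.5)), 5)
  expect_equal(st$x, 0.8 * 2, tolerance = 1e-12)

  # q -> 0 with invertible H: the update trusts the observation fully
  model2 <- list(A = diag(2), W = diag(2), H = matrix(c(2, 0, 0, 4), 2),
                 Q = diag(1e-12, 2), feature_mean = c(0, 0), d = 2L, p = 2L,
                 ridge_lambda = 0)
  class(model2) <- "kalman_model"
  st2 <- kalman_step(model2, list(x = c(0, 0), P = diag(2)), c(2, 4))
  expect_equal(st2$x, c(1, 1), tolerance = 1e-5)
})

test_that("run_kalman matches the independent brute-force Gaussian recursion", {
  worst <- 0
  for (s in 1:100) {
    inst <- random_kalman_instance(s)
    model <- list(A = inst$A, W = inst$W, H = inst$H, Q = inst$Q,
                  feature_mean = rep(0, inst$p), d = inst$d, p = inst$p,
                  ridge_lambda = 0)
    class(model) <- "kalman_model"
    mine <- run_kalman(model, inst$Z, jitter = 0)
    ref <- oracle_kalman(inst$A, inst$W, inst$H, inst$Q, inst$Z,
                         x0 = rep(0, inst$d), P0 = inst$W)
    worst <- max(worst, max(abs(mine - ref)))
  }
  expect_lt(worst, 1e-8)
})

test_that("run_kalman agrees with iterated kalman_step", {
  inst <- random_kalman_instance(7)
  model <- list(A = inst$A, W = inst$W, H = inst$H, Q = inst$Q,
                feature_mean = rep(0, inst$p), d = inst$d, p = inst$p,
                ridge_lambda = 0)
  class(model) <- "kalman_model"
  mine <- run_kalman(model, inst$Z, jitter = 0)
  st <- list(x = rep(0, inst$d), P = inst$W)
  for (t in seq_len(nrow(inst$Z))) {
    st <- kalman_step(model, st, inst$Z[t, ])
    expect_equal(st$x, mine[t, ], tolerance = 1e-9)
  }
})

test_that("the steady-state fast path matches the full iteration", {
  inst <- random_kalman_instance(3, T_max = 50)
  Zlong <- inst$Z[rep(seq_len(inst$T_), length.out = 300), , drop = FALSE]
  model <- list(A = inst$A, W = inst$W, H = inst$H, Q = inst$Q,
                feature_mean = rep(0, inst$p), d = inst$d, p = inst$p,
                ridge_lambda = 0)
  class(model) <- "kalman_model"
  full <- run_kalman(model, Zlong)
  fast <- run_kalman(model, Zlong, steady_state = TRUE)
  expect_lt(max(abs(full[101:300, ] - fast[101:300, ])), 1e-5)
})

test_that("noiseless observations drive the filter to the true state", {
  set.seed(4)
  T_ <- 400
  x <- sin(seq(0, 6 * pi, length.out = T_))
  X <- matrix(x)
  Z <- 2 * X
  m <- fit_kalman(Z, X, ridge_lambda = 0)
  m$Q <- matrix(pmax(m$Q, 1e-10))
  pred <- run_kalman(m, Z)
  expect_lt(max(abs(pred[100:T_, 1] - x[100:T_])), 0.02)
})

test_that("the error covariance stays symmetric PSD over many steps", {
  inst <- random_kalman_instance(12)
  model <- list(A = inst$A, W = inst$W, H = inst$H, Q = inst$Q,
                feature_mean = rep(0, inst$p), d = inst$d, p = inst$p,
                ridge_lambda = 0)
  class(model) <- "kalman_model"
  st <- list(x = rep(0, inst$d), P = inst$W)
  set.seed(1)
  min_eig <- Inf
  for (t in 1:10000) {
    st <- kalman_step(model, st, rnorm(inst$p))
    if (t %% 100 == 0) {
      expect_equal(st$P, t(st$P))
      min_eig <- min(min_eig, min(eigen(st$P, symmetric = TRUE)$values))
    }
  }
  expect_gte(min_eig, -1e-10)
})

test_that("a high-SNR synthetic session is decoded with low intended error", {
  # noise floor 10x below default; train and decode the same session
  cfg <- tiny_generator(seed = 77, baseline_noise_sd = 0.022,
                        trial_gain_sd = 0, tracking_error_scale = 0,
                        baseline_drift_sd = 0, cc_trial_sd = 0)
  kin <- generate_session("medium", 3, seed = 77)
  rec <- emg_forward_model(kin, cfg)
  ds <- preprocess_recording(rec, filter_spec(cfg$fs_emg))
  ds$trial_table <- attr(kin, "trial_table")
  m <- fit_kalman(ds$Z, ds$X, blocks = ds$block_id)
  pred <- run_kalman(m, ds$Z)
  trials <- lapply(unique(na.omit(ds$block_id)), function(id) {
    keep <- which(ds$block_id == id)
    trial_prediction(pred[keep, , drop = FALSE], ds$X[keep, , drop = FALSE],
                     ds$trial_table$dof[ds$trial_table$trial_id == id])
  })
  expect_lt(intended_rmse(trials), 0.15)
})

test_that("the MKF threshold map matches its defining examples and properties", {
  expect_equal(apply_mkf_threshold(0.1), 0)
  expect_equal(apply_mkf_threshold(0.2), 0)
  expect_equal(apply_mkf_threshold(-0.6), -0.5)
  expect_equal(apply_mkf_threshold(c(-1, 1)), c(-1, 1))

  x <- seq(-1, 1, by = 0.001)
  y <- apply_mkf_threshold(x)
  expect_equal(y, -rev(y))                       # odd
  expect_true(all(diff(y) >= 0))                 # monotone nondecreasing
  expect_lt(max(abs(diff(y))), 0.002)            # continuous (no jumps)
  expect_true(all(y >= -1 & y <= 1))

  # rescale = FALSE passes supra-threshold values through
  expect_equal(apply_mkf_threshold(0.6, rescale = FALSE), 0.6)
  expect_error(apply_mkf_threshold(0.5, threshold = 1), "threshold < 1")
})
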