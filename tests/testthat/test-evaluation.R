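make_trial <- function(pred_active, target_active = NULL, dof = 1, d = 3,
                       pred_rest = 0, speed = "slow") {
  T_ <- length(pred_active)
  if (is.null(target_active)) target_active <- numeric(T_)
  pred <- matrix(pred_rest, T_, d)
  pred[, dof] <- pred_active
  target <- matrix(0, T_, d)
  target[, dof] <- target_active
  trial_prediction(pred, target, dof, speed = speed)
}

test_that("intended RMSE matches constant-offset and Monte-Carlo closed forms", {
  tgt <- sin(seq(0, 2 * pi, length.out = 200))
  expect_equal(intended_rmse(make_trial(tgt, tgt)), 0)
  expect_equal(intended_rmse(make_trial(tgt + 0.1, tgt)), 0.1, tolerance = 1e-12)

  set.seed(31)
  noise <- rnorm(1e4, 0, 0.05)
  expect_equal(intended_rmse(make_trial(tgt[1] + 0, tgt[1])), 0)
  tr <- make_trial(rep(0, 1e4) + noise, rep(0, 1e4))
  expect_equal(intended_rmse(tr), 0.05, tolerance = 0.002)

  expect_error(intended_rmse(list()), "empty")
})

test_that("unintended RMSE pools the resting DOFs", {
  tgt <- rep(0.5, 100)
  tr <- make_trial(tgt, tgt, dof = 1)
  tr$pred[, 2] <- 0.3            # one resting DOF off by 0.3, the other at 0
  expect_equal(unintended_rmse(tr), sqrt(0.3^2 / 2), tolerance = 1e-12)
  tr$pred[, 2] <- 0
  expect_equal(unintended_rmse(tr), 0)
})

test_that("cross-talk in the generator raises unintended RMSE", {
  # paired comparison: identical seeds, mixing with vs without channel leak
  run_world <- function(crosstalk) {
    cfg <- generator_config(
      n_channels = 8,
      mixing = default_mixing(8, crosstalk = crosstalk, seed = 5),
      seed = 5, cocontraction_gain = 0, tracking_error_scale = 0,
      baseline_drift_sd = 0, cc_trial_sd = 0, trial_gain_sd = 0)
    kin <- generate_session("medium", 2, seed = 5)
    ds <- preprocess_recording(emg_forward_model(kin, cfg),
                               filter_spec(cfg$fs_emg))
    tab <- attr(kin, "trial_table")
    m <- fit_kalman(ds$Z, ds$X, blocks = ds$block_id)
    pred <- run_kalman(m, ds$Z)
    trials <- lapply(unique(na.omit(ds$block_id)), function(id) {
      keep <- which(ds$block_id == id)
      trial_prediction(pred[keep, , drop = FALSE], ds$X[keep, , drop = FALSE],
                       tab$dof[tab$trial_id == id])
    })
    unintended_rmse(trials)
  }
  expect_gt(run_world(0.1), run_world(0))
})

test_that("windowed RMSE implements the 15% dead band with hinge distance", {
  tgt <- rep(0.2, 500)
  # inside the window everywhere (|err| <= 0.15 * 2) -> zero
  expect_equal(windowed_rmse(make_trial(tgt + 0.29, tgt)), 0)
  # exactly at the window edge -> zero
  expect_equal(windowed_rmse(make_trial(tgt + 0.3, tgt)), 0)
  # offset of 0.20 * full range = 0.4 -> hinge distance 0.1 = 0.05 * range
  expect_equal(windowed_rmse(make_trial(tgt + 0.4, tgt)), 0.1, tolerance = 1e-12)
  # the full-deviation convention is available behind a flag
  expect_equal(windowed_rmse(make_trial(tgt + 0.4, tgt), hinge = FALSE), 0.4)
})

test_that("windowed RMSE never exceeds intended RMSE", {
  set.seed(8)
  for (k in 1:20) {
    tgt <- cumsum(rnorm(100, 0, 0.05))
    tr <- make_trial(tgt + rnorm(100, 0, 0.3), tgt)
    expect_lte(windowed_rmse(tr), intended_rmse(tr))
  }
})

test_that("RMSE metrics are invariant to trial order", {
  set.seed(9)
  trials <- lapply(1:5, function(i)
    make_trial(rnorm(50), rnorm(50), dof = sample(3, 1)))
  perm <- trials[c(3, 1, 5, 2, 4)]
  expect_equal(intended_rmse(trials), intended_rmse(perm))
  expect_equal(unintended_rmse(trials), unintended_rmse(perm))
  expect_equal(windowed_rmse(trials), windowed_rmse(perm))
})

test_that("LMAJ matches the analytic jerk of t^3 and its scaling law", {
  fs <- 30
  t <- seq(0, 2, by = 1 / fs)
  x <- t^3                       # third derivative = 6 everywhere
  expect_equal(lmaj(x, fs), log(6), tolerance = 0.01)
  # log scaling identity
  expect_equal(lmaj(5 * x, fs), lmaj(x, fs) + log(5), tolerance = 1e-9)
  # constant trajectory floors at log(eps)
  expect_equal(lmaj(rep(1, 100), fs), log(1e-12))
  expect_error(lmaj(c(1, 2, 3), fs), "at least 4")
})

test_that("smoothing a noisy trajectory lowers LMAJ", {
  set.seed(10)
  fs <- 30
  x <- sin(seq(0, 4 * pi, length.out = 300)) + rnorm(300, 0, 0.2)
  sm <- stats::filter(x, rep(1 / 7, 7), sides = 2)
  sm <- as.numeric(na.omit(sm))
  expect_lt(lmaj(sm, fs), lmaj(x, fs))
})

test_that("time normalization preserves linear ramps and endpoints", {
  ramp <- seq(-1, 1, length.out = 37)
  out <- time_normalize_trials(list(ramp), 101)
  expect_lt(max(abs(out[1, ] - seq(-1, 1, length.out = 101))), 1e-10)

  same <- time_normalize_trials(list(ramp), 37)
  expect_equal(same[1, ], ramp, tolerance = 1e-12)

  slow <- sin(seq(0, pi, length.out = 210))   # 7 s at 30 Hz
  fast <- sin(seq(0, pi, length.out = 60))    # 2 s at 30 Hz
  M <- time_normalize_trials(list(slow, fast), 100)
  expect_equal(dim(M), c(2, 100))
  expect_equal(M[, 1], c(slow[1], fast[1]))
  expect_equal(M[, 100], c(tail(slow, 1), tail(fast, 1)))
})

test_that("SnPM finds nothing under identity and everything under a huge shift", {
  set.seed(12)
  n <- 8; T_ <- 40
  tgt <- matrix(rnorm(n * T_), n, T_)
  r0 <- suppressWarnings(snpm_paired_t(tgt, tgt))
  expect_false(any(r0$sig_mask))

  pred <- tgt + 10 + matrix(rnorm(n * T_), n, T_)   # 10 SD shift plus noise
  r1 <- snpm_paired_t(pred, tgt)
  expect_true(all(r1$sig_mask))
  expect_true(r1$exhaustive)   # 2^8 = 256 <= default budget
})

test_that("exhaustive enumeration matches the Monte-Carlo critical value", {
  set.seed(13)
  n <- 10; T_ <- 30
  D <- matrix(rnorm(n * T_), n, T_)
  tgt <- matrix(0, n, T_)
  ex <- snpm_paired_t(D, tgt, n_perm = 2^n)          # exhaustive
  mc <- snpm_paired_t(D, tgt, n_perm = 1023, seed = 99)  # forced Monte-Carlo
  expect_true(ex$exhaustive); expect_false(mc$exhaustive)
  expect_equal(ex$crit, mc$crit, tolerance = 0.15)
})

test_that("SnPM controls the family-wise type-I error at alpha", {
  set.seed(14)
  n <- 10; T_ <- 100; reps <- 300
  rejections <- 0
  for (r in seq_len(reps)) {
    D <- matrix(rnorm(n * T_), n, T_)
    res <- snpm_paired_t(D, matrix(0, n, T_), n_perm = 1024)
    rejections <- rejections + any(res$sig_mask)
  }
  rate <- rejections / reps
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("zero-variance time points yield t = 0 with a warning", {
  n <- 6; T_ <- 10
  pred <- matrix(rnorm(n * T_), n, T_)
  tgt <- pred
  pred[, 3] <- tgt[, 3] + 0   # zero differences -> zero variance
  pred[, -3] <- pred[, -3] + rnorm(n * (T_ - 1), 0, 1)
  expect_warning(res <- snpm_paired_t(pred, tgt), "zero-variance")
  expect_equal(res$t_trace[3], 0)
})
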