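test_that("speed presets have the published rise/hold/fall durations", {
  expect_equal(make_speed_profile("slow")$total_s, 7)
  expect_equal(make_speed_profile("medium")$total_s, 4)
  expect_equal(make_speed_profile("fast")$total_s, 2)
  expect_equal(unlist(make_speed_profile("slow")[c("rise_s", "hold_s", "fall_s")],
                      use.names = FALSE), c(3, 1, 3))
  expect_equal(unlist(make_speed_profile("fast")[c("rise_s", "hold_s", "fall_s")],
                      use.names = FALSE), c(0.5, 1, 0.5))
  expect_error(make_speed_profile("brisk"), "unknown speed")
})

test_that("trial trajectories ramp linearly, hold at the endpoint and rest at zero", {
  mv <- movement_specs()
  for (sp in c("slow", "medium", "fast")) {
    for (m in c(1, 4)) {  # grasp (+1) and wrist extend (-1)
      prof <- make_speed_profile(sp)
      tr <- generate_trial_trajectory(prof, mv[m, ], lead_rest_s = 1)
      dof <- mv$dof[m]; dir <- mv$direction[m]
      expect_true(all(abs(tr$x) <= 1))
      expect_true(all(tr$x[, setdiff(1:3, dof)] == 0))
      expect_true(all(tr$x[tr$phase == "hold", dof] == dir))
      expect_true(all(tr$x[tr$phase == "rest", ] == 0))
      expect_equal(tail(tr$x[, dof], 1), 0)
      # linear ramp: value at exactly half the rise time (oracle: evaluate
      # the ramp formula by interpolating the sampled trajectory)
      half <- approx(tr$t, tr$x[, dof], xout = 1 + prof$rise_s / 2)$y
      expect_equal(half, dir * 0.5, tolerance = 1e-12)
    }
  }
})

test_that("minimum-jerk ramps are available and preserve the endpoints", {
  tr <- generate_trial_trajectory(make_speed_profile("fast"), movement_specs()[1, ],
                                  ramp = "minjerk")
  expect_true(all(tr$x[tr$phase == "hold", 1] == 1))
  expect_equal(tail(tr$x[, 1], 1), 0)
  expect_true(all(diff(tr$x[tr$phase == "rise", 1]) >= 0))
})

test_that("sessions contain n trials of each movement in a seeded order", {
  ses <- generate_session("medium", 20, seed = 3)
  tab <- attr(ses, "trial_table")
  expect_equal(nrow(tab), 120)                 # 20 x 6 movements
  expect_equal(unname(table(tab$movement)), rep(20L, 6), ignore_attr = TRUE)

  ses1 <- generate_session("fast", 1, seed = 5)
  expect_equal(nrow(attr(ses1, "trial_table")), 6)

  # label counting on the samples themselves
  ids <- unique(na.omit(ses1$trial_id))
  expect_length(ids, 6)

  # seeded determinism of the trial order
  sesA <- generate_session("slow", 3, seed = 11)
  sesB <- generate_session("slow", 3, seed = 11)
  expect_identical(attr(sesA, "trial_table"), attr(sesB, "trial_table"))
  expect_identical(sesA$x, sesB$x)
})

test_that("forward model is silent with no drive, no noise and no line", {
  kin <- tiny_session("fast", 1, seed = 1)
  kin$x[] <- 0
  kin$phase[] <- "rest"
  kin$active_dof[] <- NA_integer_
  cfg <- tiny_generator(baseline_noise_sd = 0, line_amp = 0,
                        tracking_error_scale = 0, baseline_drift_sd = 0)
  rec <- emg_forward_model(kin, cfg)
  expect_true(all(rec$v == 0))
})

test_that("hold-phase variance matches the closed-form envelope", {
  # constant hold at x = +1 with no velocity drive: per-channel variance
  # must equal baseline^2 + (mixing %*% position drive)^2 within 5%
  prof <- make_speed_profile("slow")
  kin <- generate_trial_trajectory(prof, movement_specs()[1, ], fs_kin = 30)
  # stretch the hold by repeating hold samples to get >= 10^4 EMG samples
  hold <- which(kin$phase == "hold")
  idx <- c(seq_len(min(hold) - 1), rep(hold, length.out = 400))
  kin2 <- kin
  kin2$t <- seq_along(idx) / kin$fs
  kin2$x <- kin$x[idx, , drop = FALSE]
  kin2$phase <- kin$phase[idx]
  kin2$active_dof <- kin$active_dof[idx]
  kin2$active_movement <- kin$active_movement[idx]
  kin2$trial_id <- kin$trial_id[idx]
  kin2$block_id <- kin$block_id[idx]
  cfg <- tiny_generator(seed = 8, velocity_gain = 0, line_amp = 0,
                        trial_gain_sd = 0, tracking_error_scale = 0,
                        baseline_drift_sd = 0, cocontraction_gain = 0)
  rec <- emg_forward_model(kin2, cfg)
  idx <- pmin(length(kin2$phase),
              pmax(1L, ceiling(seq_len(nrow(rec$v)) / cfg$fs_emg * cfg$fs_kin)))
  # trim a frame on each side of the hold so interpolation edges are excluded
  hold_frames <- which(kin2$phase == "hold")
  hold_emg <- which(idx %in% hold_frames[3:(length(hold_frames) - 2)])
  expect_gt(length(hold_emg), 1e4)
  v_emp <- apply(rec$v[hold_emg, ], 2, var)
  v_theory <- cfg$baseline_noise_sd^2 +
    (cfg$mixing[, 1] * cfg$position_gain)^2
  expect_equal(v_emp, v_theory, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("the forward model is bit-identical under the same seed", {
  kin <- tiny_session("medium", 1, seed = 2)
  cfg <- tiny_generator(seed = 123)
  r1 <- emg_forward_model(kin, cfg)
  r2 <- emg_forward_model(kin, cfg)
  expect_identical(r1$v, r2$v)
})

test_that("velocity gain raises transition EMG but leaves hold statistics alone", {
  kin <- tiny_session("fast", 2, seed = 4)
  up <- function(lbl, n, fs_emg = 1000, fs_kin = 30) {
    lbl[pmin(length(lbl), pmax(1L, ceiling(seq_len(n) / fs_emg * fs_kin)))]
  }
  means_rise <- c(); means_hold <- c()
  for (vg in c(0.2, 0.8)) {
    abs_sum <- 0
    rise_m <- 0; hold_m <- 0
    for (rep_i in 1:20) {
      cfg <- tiny_generator(seed = 300 + rep_i, velocity_gain = vg,
                            line_amp = 0, trial_gain_sd = 0,
                            tracking_error_scale = 0, baseline_drift_sd = 0)
      rec <- emg_forward_model(kin, cfg)
      ph <- up(kin$phase, nrow(rec$v))
      rise_m <- rise_m + mean(abs(rec$v[ph %in% c("rise", "fall"), ]))
      hold_m <- hold_m + mean(abs(rec$v[ph == "hold", ]))
    }
    means_rise <- c(means_rise, rise_m / 20)
    means_hold <- c(means_hold, hold_m / 20)
  }
  expect_gt(means_rise[2], means_rise[1])
  expect_equal(means_hold[2], means_hold[1], tolerance = 0.02)
})

test_that("fast trials produce larger transition EMG than slow trials", {
  ok <- 0
  for (rep_i in 1:5) {
    cfg <- tiny_generator(seed = 600 + rep_i)
    rise_mean <- sapply(c("slow", "fast"), function(sp) {
      kin <- generate_session(sp, 1, seed = 600 + rep_i)
      rec <- emg_forward_model(kin, cfg)
      idx <- pmin(length(kin$phase),
                  pmax(1L, ceiling(seq_len(nrow(rec$v)) / 1000 * 30)))
      ph <- kin$phase[idx]
      mean(abs(rec$v[ph %in% c("rise", "fall"), ]))
    })
    ok <- ok + (rise_mean["fast"] > rise_mean["slow"])
  }
  expect_gte(ok, 4)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(mixing = matrix(1, 4, 6)), "n_channels x 6")
  expect_error(generator_config(position_gain = -1), "nonnegative")
  bad_mix <- matrix(1, 32, 6)  # rank 1
  expect_error(generator_config(mixing = bad_mix), "full column rank")
})
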