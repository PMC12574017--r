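#' Default block-structured mixing matrix
#'
#' Maps the six directional movements onto EMG channels: each movement drives
#' a dominant block of channels with unit gain (about five channels per
#' movement, like a forearm muscle group) plus small cross-talk gains of about
#' 10% on the remaining channels, so movements are separable but not
#' orthogonal. Fixed by `seed`.
#'
#' @param n_channels number of EMG channels (default 32).
#' @param crosstalk mean cross-talk gain (default 0.1); draws are uniform on
#'   `[0, 2 * crosstalk]`.
#' @param seed integer seed.
#' @return an `n_channels` x 6 nonnegative matrix of full column rank.
#' @export
default_mixing <- function(n_channels = 32, crosstalk = 0.1, seed = 1) {
  stopifnot(n_channels >= 6)
  set.seed(derive_seed(seed, 17L))
  M <- matrix(runif(n_channels * 6, 0, 2 * crosstalk), n_channels, 6)
  block <- max(1L, floor(n_channels / 6))
  for (m in 1:6) {
    lo <- (m - 1L) * block + 1L
    hi <- min(n_channels, m * block)
    M[lo:hi, m] <- runif(hi - lo + 1, 0.8, 1.2)
  }
  M
}

#' Configuration of the synthetic EMG forward model
#'
#' The forward model renders each channel as envelope-modulated white noise:
#' `v_c(t) = g_trial * envelope_c(t) * n(t) + line_amp * sin(2*pi*60*t)`,
#' with `envelope_c = sqrt(baseline_noise_sd^2 + drive_c^2)` and
#' `drive_c = sum_m mixing[c, m] * a_m + cc_weights[c] * cc(t)`.
#' Movement activations `a_m` combine a rectified position drive and a
#' rectified velocity drive, so fast movements (large velocities) produce
#' larger, more distinct EMG while slow movements are subtler and relatively
#' noisier. `cc(t) = cocontraction_gain * sum_d |dx_d/dt|` is a nonspecific
#' co-contraction drive shared across all channels, emulating the
#' antagonist/stabilizer co-activation that accompanies ballistic movement
#' and degrades the muscle-specificity of fast-movement EMG.
#'
#' @param n_channels channels (default 32).
#' @param fs_emg EMG rate in Hz (default 1000).
#' @param fs_kin kinematic rate in Hz (default 30).
#' @param mixing `n_channels` x 6 nonnegative gain matrix; default
#'   [default_mixing()] built from `seed`.
#' @param baseline_noise_sd resting envelope floor (default 0.22; a slow
#'   hold's position drive then sits only about 2:1 above the floor, making
#'   slow-speed EMG the subtler, relatively noisier signal).
#' @param position_gain,velocity_gain weights of the rectified position and
#'   velocity drives (defaults 0.45 and 0.35; peak target velocities are
#'   1/3, 2/3 and 2 units/s for slow/medium/fast, so the velocity drive
#'   dominates fast transitions).
#' @param cocontraction_gain weight of the speed-scaled nonspecific drive
#'   (default 1.0).
#' @param cc_weights per-channel weights of the co-contraction drive; default
#'   uniform draws on [0.5, 1.5], fixed by `seed`.
#' @param tracking_error_scale optional mimicked-training execution error,
#'   in kinematic units per second of ramp time (default 0: off). When
#'   positive, the EMG is driven by the movement the subject actually
#'   executes, which deviates from the displayed (label) trajectory by a
#'   smooth tracking error with per-trial spread
#'   `tracking_error_scale * rise_s`, so long slow ramps are followed
#'   imprecisely while ballistic fast movements stay stereotyped.
#'   Ground-truth labels remain the ideal trapezoid.
#' @param baseline_drift_sd optional relative spread of a slow (about 1 Hz)
#'   additive drift of each channel's resting envelope floor (default 0:
#'   off), emulating baseline tone, posture shifts and electrode impedance
#'   drift.
#' @param cc_trial_sd trial-to-trial spread of the co-contraction amplitude
#'   (default 0.4): each trial's nonspecific drive is additionally scaled by
#'   `1 + N(0, cc_trial_sd)`, reflecting how variable ballistic
#'   co-activation is from repetition to repetition.
#' @param line_amp amplitude of 60 Hz line interference (default 0.15).
#' @param trial_gain_sd trial-to-trial multiplicative gain spread
#'   (default 0.15): each trial's drive is scaled by `1 + N(0, trial_gain_sd)`.
#' @param seed master RNG seed; per-trial streams are derived by counter so
#'   changing the trial count does not reshuffle earlier trials.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_channels = 32, fs_emg = 1000, fs_kin = 30,
                             mixing = NULL, baseline_noise_sd = 0.22,
                             position_gain = 0.45, velocity_gain = 0.35,
                             cocontraction_gain = 1.0, cc_weights = NULL,
                             tracking_error_scale = 0,
                             baseline_drift_sd = 0, cc_trial_sd = 0.4,
                             line_amp = 0.15, trial_gain_sd = 0.15, seed = 1) {
  if (is.null(mixing)) mixing <- default_mixing(n_channels, seed = seed)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_channels || ncol(mixing) != 6) {
    stop("mixing must be n_channels x 6 (got ", nrow(mixing), " x ",
         ncol(mixing), ")")
  }
  if (any(mixing < 0)) stop("mixing gains must be nonnegative")
  if (qr(mixing)$rank < 6) stop("mixing must have full column rank")
  gains <- c(baseline_noise_sd, position_gain, velocity_gain,
             cocontraction_gain, tracking_error_scale, baseline_drift_sd,
             cc_trial_sd, line_amp, trial_gain_sd)
  if (any(gains < 0)) stop("all gains must be nonnegative")
  if (is.null(cc_weights)) {
    set.seed(derive_seed(seed, 23L))
    cc_weights <- runif(n_channels, 0.5, 1.5)
  }
  stopifnot(length(cc_weights) == n_channels, all(cc_weights >= 0))
  out <- list(
    n_channels = n_channels, fs_emg = fs_emg, fs_kin = fs_kin,
    mixing = mixing, baseline_noise_sd = baseline_noise_sd,
    position_gain = position_gain, velocity_gain = velocity_gain,
    cocontraction_gain = cocontraction_gain, cc_weights = cc_weights,
    tracking_error_scale = tracking_error_scale,
    baseline_drift_sd = baseline_drift_sd, cc_trial_sd = cc_trial_sd,
    line_amp = line_amp, trial_gain_sd = trial_gain_sd, seed = seed
  )
  class(out) <- "generator_config"
  out
}

# Per-movement rectified activations at the kinematic rate.
# Returns list(act = T x 6 matrix, cc = length-T co-contraction drive).
movement_activations <- function(kin, cfg) {
  X <- kin$x
  V <- rbind(0, diff(X)) * kin$fs
  mv <- movement_specs()
  act <- matrix(0, nrow(X), 6)
  for (m in 1:6) {
    d <- mv$dof[m]; s <- mv$direction[m]
    act[, m] <- cfg$position_gain * pmax(0, s * X[, d]) +
      cfg$velocity_gain * pmax(0, s * V[, d])
  }
  cc <- cfg$cocontraction_gain * rowSums(abs(V))
  list(act = act, cc = cc)
}

#' Render raw EMG from a kinematic trajectory
#'
#' Applies the envelope-modulated-noise forward model described in
#' [generator_config()]. The per-channel drive is computed at the kinematic
#' rate, scaled by a per-trial gain `1 + N(0, trial_gain_sd)` (stream derived
#' from `cfg$seed` and the trial counter), linearly interpolated up to
#' `fs_emg`, converted to an envelope
#' `sqrt(baseline_noise_sd^2 + drive^2)`, multiplied by unit-variance white
#' noise, and summed with 60 Hz line interference. Fully determined by
#' `cfg$seed`.
#'
#' @param kin a `kin_trajectory`.
#' @param cfg a [generator_config()].
#' @return an object of class `emg_recording`: list with `t` (seconds at
#'   `fs_emg`), `v` (n_samples x n_channels matrix), `fs`, `kin` (the
#'   generating trajectory) and `seed_used`.
#' @export
emg_forward_model <- function(kin, cfg) {
  stopifnot(inherits(kin, "kin_trajectory"), inherits(cfg, "generator_config"))
  if (abs(kin$fs - cfg$fs_kin) > 1e-9) {
    stop("kinematic rate of trajectory (", kin$fs, " Hz) does not match cfg$fs_kin (",
         cfg$fs_kin, " Hz)")
  }
  # executed kinematics: the subject's actual movement deviates from the
  # displayed label trajectory by a smooth per-trial tracking error on the
  # active DOF, scaled by the profile's ramp duration (slow trials are
  # followed imprecisely, ballistic fast trials are stereotyped)
  kin_exec <- kin
  if (cfg$tracking_error_scale > 0 && !is.null(kin$speed)) {
    prof <- make_speed_profile(kin$speed)
    sd_tr <- cfg$tracking_error_scale * prof$rise_s
    moving <- kin$phase != "rest"
    if (any(moving)) {
      set.seed(derive_seed(cfg$seed, 5L))
      t_knot <- seq(0, max(kin$t) + 1, by = 1)
      wob <- vapply(1:3, function(d)
        approx(t_knot, rnorm(length(t_knot), 0, sd_tr), xout = kin$t,
               rule = 2)$y, numeric(length(kin$t)))
      for (d in 1:3) {
        sel <- moving & kin$active_dof == d
        kin_exec$x[sel, d] <- pmin(1, pmax(-1, kin$x[sel, d] + wob[sel, d]))
      }
    }
  }

  a <- movement_activations(kin_exec, cfg)

  # per-trial multiplicative gains, counter-derived streams: an overall
  # effort gain plus an independent co-contraction amplitude
  ids <- kin$trial_id
  trials <- sort(unique(ids[!is.na(ids)]))
  gain <- rep(1, length(kin$t))
  cc_gain <- rep(1, length(kin$t))
  for (k in trials) {
    set.seed(derive_seed(cfg$seed, 1000L + k))
    sel <- !is.na(ids) & ids == k
    gain[sel] <- max(0, 1 + rnorm(1, 0, cfg$trial_gain_sd))
    cc_gain[sel] <- max(0, 1 + rnorm(1, 0, cfg$cc_trial_sd))
  }
  drive <- (a$act %*% t(cfg$mixing)) * gain +
    outer(a$cc * gain * cc_gain, cfg$cc_weights)

  # upsample drive to the EMG rate by linear interpolation
  n_emg <- round(length(kin$t) / kin$fs * cfg$fs_emg)
  t_emg <- seq_len(n_emg) / cfg$fs_emg
  drive_up <- apply(drive, 2, function(col) {
    approx(kin$t, col, xout = t_emg, rule = 2)$y
  })

  # slow additive drift of the per-channel envelope floor: Gaussian knots
  # every 0.5 s, linearly interpolated (band-limited to about 1 Hz)
  floor_up <- cfg$baseline_noise_sd
  if (cfg$baseline_drift_sd > 0) {
    set.seed(derive_seed(cfg$seed, 4L))
    t_knot <- seq(0, max(t_emg) + 0.5, by = 0.5)
    floor_up <- apply(
      matrix(rnorm(length(t_knot) * cfg$n_channels), length(t_knot)),
      2, function(k) approx(t_knot, k, xout = t_emg, rule = 2)$y)
    floor_up <- cfg$baseline_noise_sd *
      pmax(0, 1 + cfg$baseline_drift_sd * floor_up)
  }
  envelope <- sqrt(floor_up^2 + drive_up^2)

  set.seed(derive_seed(cfg$seed, 2L))
  noise <- matrix(rnorm(n_emg * cfg$n_channels), n_emg, cfg$n_channels)
  line <- cfg$line_amp * sin(2 * pi * 60 * t_emg)
  v <- envelope * noise + line

  out <- list(t = t_emg, v = v, fs = cfg$fs_emg, kin = kin,
              seed_used = cfg$seed)
  class(out) <- "emg_recording"
  out
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording: %d samples x %d channels @ %g Hz (%.1f s)>\n",
              nrow(x$v), ncol(x$v), x$fs, nrow(x$v) / x$fs))
  invisible(x)
}
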