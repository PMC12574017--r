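#' Bundle one trial's predictions with its ground truth
#'
#' @param pred frames x d matrix of predicted kinematics.
#' @param target frames x d matrix of ground-truth kinematics.
#' @param active_dof the trial's intended DOF (1..d).
#' @param trial_id,speed optional labels.
#' @return object of class `trial_prediction`.
#' @export
trial_prediction <- function(pred, target, active_dof, trial_id = NA,
                             speed = NA) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(all(dim(pred) == dim(target)),
            active_dof >= 1, active_dof <= ncol(pred))
  out <- list(pred = pred, target = target,
              active_dof = as.integer(active_dof),
              trial_id = trial_id, speed = speed)
  class(out) <- "trial_prediction"
  out
}

as_trial_list <- function(trials) {
  if (inherits(trials, "trial_prediction")) trials <- list(trials)
  if (length(trials) < 1) stop("empty trial list")
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_prediction")))
  trials
}

#' Intended-movement RMSE
#'
#' Root mean squared error between predicted and target kinematics on each
#' trial's intended (active) DOF, pooled across trials, in normalized range
#' units (the [-1, 1] kinematic units; full span = 2). Captures how
#' precisely the decoded DOF follows the movement it is supposed to make.
#'
#' @param trials a `trial_prediction` or list of them.
#' @return a nonnegative scalar.
#' @export
intended_rmse <- function(trials) {
  trials <- as_trial_list(trials)
  se <- unlist(lapply(trials, function(tr) {
    (tr$pred[, tr$active_dof] - tr$target[, tr$active_dof])^2
  }))
  sqrt(mean(se))
}

#' Unintended-movement RMSE (cross-talk)
#'
#' As [intended_rmse()] but pooled over each trial's non-active DOFs, whose
#' targets are zero throughout; captures leakage of activity onto DOFs that
#' should stay at rest.
#'
#' @param trials a `trial_prediction` or list of them.
#' @return a nonnegative scalar.
#' @export
unintended_rmse <- function(trials) {
  trials <- as_trial_list(trials)
  se <- unlist(lapply(trials, function(tr) {
    rest <- setdiff(seq_len(ncol(tr$pred)), tr$active_dof)
    (tr$pred[, rest, drop = FALSE] - tr$target[, rest, drop = FALSE])^2
  }))
  sqrt(mean(se))
}

#' Dead-band (error-window) RMSE
#'
#' RMSE on the intended DOF where per-sample error is the hinge distance
#' outside a +/- `window_frac` band of the full kinematic range:
#' `max(0, |pred - target| - window_frac * 2)`. Samples anywhere inside the
#' 15% window (the default) therefore contribute zero error, matching
#' target-tracking feedback where a DOF "in the window" is on target.
#' Set `hinge = FALSE` to count the full deviation once outside the band.
#'
#' @param trials a `trial_prediction` or list of them.
#' @param window_frac half-width of the window as a fraction of the full
#'   range (default 0.15).
#' @param full_range full kinematic span (default 2, the [-1, 1] range).
#' @param hinge measure distance outside the band (default TRUE) rather than
#'   full deviation.
#' @return a nonnegative scalar, at most [intended_rmse()] on the same input.
#' @export
windowed_rmse <- function(trials, window_frac = 0.15, full_range = 2,
                          hinge = TRUE) {
  stopifnot(window_frac >= 0, window_frac < 1)
  trials <- as_trial_list(trials)
  band <- window_frac * full_range
  se <- unlist(lapply(trials, function(tr) {
    dev <- abs(tr$pred[, tr$active_dof] - tr$target[, tr$active_dof])
    err <- if (hinge) pmax(0, dev - band) else ifelse(dev > band, dev, 0)
    err^2
  }))
  sqrt(mean(se))
}

#' Log mean absolute jerk of a trajectory
#'
#' Jerk is the third time-derivative, estimated by third-order finite
#' differences scaled by `fs^3`; LMAJ is `log(mean(|jerk|) + eps)` with a
#' small floor so a perfectly constant trajectory stays finite. Lower values
#' mean smoother control.
#'
#' @param traj numeric vector, a single-DOF time series (length >= 4).
#' @param fs sampling rate, Hz.
#' @param eps floor inside the log (default 1e-12).
#' @return a scalar (natural log).
#' @export
lmaj <- function(traj, fs, eps = 1e-12) {
  traj <- as.numeric(traj)
  if (length(traj) < 4) stop("need at least 4 samples for a third difference")
  jerk <- diff(traj, differences = 3) * fs^3
  log(mean(abs(jerk)) + eps)
}

#' Resample trials to a common time base
#'
#' Linearly interpolates each trial onto `T_common` equally spaced phase
#' points spanning its own duration, so trials of different speeds can be
#' compared point by point (endpoints are preserved exactly).
#'
#' @param trials list of numeric vectors (each length >= 2).
#' @param T_common number of output points.
#' @return an n x `T_common` matrix, one row per trial.
#' @export
time_normalize_trials <- function(trials, T_common) {
  stopifnot(T_common >= 2)
  if (is.numeric(trials)) trials <- list(trials)
  out <- t(vapply(trials, function(tr) {
    tr <- as.numeric(tr)
    if (length(tr) < 2) stop("each trial needs at least 2 frames")
    approx(seq(0, 1, length.out = length(tr)), tr,
           xout = seq(0, 1, length.out = T_common))$y
  }, numeric(T_common)))
  out
}

#' Statistical non-parametric mapping: paired permutation t-map
#'
#' Computes a paired t statistic at every time point between predicted and
#' target traces (n trials, time-normalized to a common length), and
#' controls the family-wise error over time with the permutation
#' distribution of the maximum absolute t under random sign flips of whole
#' trials. When `2^n <= n_perm` all sign patterns are enumerated
#' exhaustively; otherwise `n_perm` random sign patterns are drawn.
#'
#' @param pred_trials n x T matrix of predicted traces.
#' @param target_trials n x T matrix of target traces.
#' @param n_perm permutation budget (default 4096).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed seed for the Monte-Carlo sign draws.
#' @return object of class `snpm_result`: `t_trace`, `crit`, `sig_mask`,
#'   `n_perm` (actually used), `alpha`, `exhaustive`.
#' @export
snpm_paired_t <- function(pred_trials, target_trials, n_perm = 4096,
                          alpha = 0.05, seed = 1) {
  P <- as.matrix(pred_trials); G <- as.matrix(target_trials)
  stopifnot(all(dim(P) == dim(G)))
  n <- nrow(P); Tn <- ncol(P)
  if (n < 2) stop("need at least 2 trials")
  D <- P - G

  msq <- colMeans(D^2)  # invariant under sign flips of whole trials

  t_of_means <- function(m) {
    v <- (msq - m^2) * n / (n - 1)
    tt <- ifelse(v <= 0, 0, m / sqrt(v / n))
    bad <- v <= .Machine$double.eps * pmax(msq, 1)
    if (any(bad)) tt[bad] <- 0
    tt
  }

  t_obs <- t_of_means(colMeans(D))
  zero_var <- (msq - colMeans(D)^2) <= .Machine$double.eps * pmax(msq, 1)
  if (any(zero_var)) {
    warning(sum(zero_var),
            " time point(s) with zero-variance differences; t set to 0")
  }

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    n_used <- 2^n
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    n_used <- n_perm
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  Mperm <- (S %*% D) / n                    # permuted means, n_used x T
  Vperm <- sweep(-(Mperm^2), 2, msq, `+`) * n / (n - 1)
  Tperm <- abs(Mperm) / sqrt(pmax(Vperm, .Machine$double.xmin) / n)
  Tperm[Vperm <= 0] <- 0
  max_t <- apply(Tperm, 1, max)
  crit <- sort(max_t)[ceiling((1 - alpha) * n_used)]

  out <- list(t_trace = t_obs, crit = crit, sig_mask = abs(t_obs) > crit,
              n_perm = n_used, alpha = alpha, exhaustive = exhaustive)
  class(out) <- "snpm_result"
  out
}

#' @export
print.snpm_result <- function(x, ...) {
  cat(sprintf("<snpm_result: %d time points, crit |t| = %.3f (alpha = %g, %s, %d perms), %d significant>\n",
              length(x$t_trace), x$crit, x$alpha,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_perm, sum(x$sig_mask)))
  invisible(x)
}
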