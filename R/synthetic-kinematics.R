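#' Speed-profile presets for trapezoidal trials
#'
#' A trial is a trapezoidal excursion of one degree of freedom (DOF): a ramp
#' from rest to the kinematic endpoint over `rise_s`, a hold of `hold_s` at
#' the endpoint, and a return ramp over `fall_s`. The three presets are
#' slow = (3, 1, 3) s, medium = (1.5, 1, 1.5) s and fast = (0.5, 1, 0.5) s,
#' i.e. total durations of 7, 4 and 2 s.
#'
#' @param name one of `"slow"`, `"medium"`, `"fast"`.
#' @return an object of class `speed_profile` with fields `name`, `rise_s`,
#'   `hold_s`, `fall_s` and `total_s`.
#' @export
make_speed_profile <- function(name) {
  presets <- list(
    slow   = c(rise_s = 3,   hold_s = 1, fall_s = 3),
    medium = c(rise_s = 1.5, hold_s = 1, fall_s = 1.5),
    fast   = c(rise_s = 0.5, hold_s = 1, fall_s = 0.5)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown speed profile '", paste(name, collapse = ","),
         "'; must be one of: ", paste(names(presets), collapse = ", "))
  }
  p <- as.list(presets[[name]])
  out <- c(list(name = name), p, list(total_s = sum(unlist(p))))
  class(out) <- "speed_profile"
  out
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile '%s': rise %.2g s, hold %.2g s, fall %.2g s (total %.2g s)>\n",
              x$name, x$rise_s, x$hold_s, x$fall_s, x$total_s))
  invisible(x)
}

#' The six directional movements of the 3-DOF hand/wrist
#'
#' DOF 1 is grasp/open, DOF 2 wrist flexion/extension, DOF 3
#' pronation/supination. Each DOF is bidirectional: +1 is maximum
#' grasp/flexion/pronation, -1 maximum open/extension/supination.
#'
#' @return a data.frame with columns `movement` (1..6), `dof` (1..3),
#'   `direction` (+1/-1) and `label`.
#' @export
movement_specs <- function() {
  data.frame(
    movement  = 1:6,
    dof       = rep(1:3, each = 2),
    direction = rep(c(1, -1), times = 3),
    label     = c("grasp", "open", "wrist_flex", "wrist_extend",
                  "pronate", "supinate"),
    stringsAsFactors = FALSE
  )
}

# Position of the active DOF at time u (seconds since movement onset),
# for a linear (constant-velocity) ramp. Vectorised over u.
trapezoid_position <- function(u, profile) {
  r <- profile$rise_s; h <- profile$hold_s; f <- profile$fall_s
  x <- numeric(length(u))
  rise <- u > 0 & u <= r
  hold <- u > r & u <= r + h
  fall <- u > r + h & u <= r + h + f
  x[rise] <- u[rise] / r
  x[hold] <- 1
  x[fall] <- 1 - (u[fall] - r - h) / f
  x
}

# Minimum-jerk ramp shape on [0,1]: 10s^3 - 15s^4 + 6s^5.
minjerk_position <- function(u, profile) {
  r <- profile$rise_s; h <- profile$hold_s; f <- profile$fall_s
  shape <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
  x <- numeric(length(u))
  rise <- u > 0 & u <= r
  hold <- u > r & u <= r + h
  fall <- u > r + h & u <= r + h + f
  x[rise] <- shape(u[rise] / r)
  x[hold] <- 1
  x[fall] <- shape(1 - (u[fall] - r - h) / f)
  x
}

#' Generate one trial trajectory
#'
#' Produces the ground-truth kinematics of a single mimicked trial: the
#' active DOF ramps from 0 to `direction * 1` over the rise phase, holds at
#' the endpoint, and returns to 0 over the fall phase; the other two DOFs are
#' identically zero. Sample times are `i / fs_kin` for `i = 1..n`, measured
#' from the start of the (optional) leading rest.
#'
#' @param profile a [make_speed_profile()] object.
#' @param movement a row of [movement_specs()], or a list with `dof` and
#'   `direction`.
#' @param fs_kin kinematic sampling rate in Hz (default 30).
#' @param lead_rest_s seconds of rest prepended before movement onset.
#' @param ramp `"linear"` (default; constant target velocity) or `"minjerk"`.
#' @return an object of class `kin_trajectory`: list with `t` (seconds),
#'   `x` (n x 3 matrix in [-1, 1]), `active_dof` (integer or NA at rest),
#'   `active_movement`, `phase` (character in rest/rise/hold/fall),
#'   `trial_id`, `block_id`, `fs` and `speed`.
#' @export
generate_trial_trajectory <- function(profile, movement, fs_kin = 30,
                                      lead_rest_s = 0,
                                      ramp = c("linear", "minjerk")) {
  stopifnot(inherits(profile, "speed_profile"), fs_kin > 0)
  ramp <- match.arg(ramp)
  dof <- as.integer(movement$dof)
  dir <- as.numeric(movement$direction)
  stopifnot(dof %in% 1:3, dir %in% c(-1, 1))

  total <- lead_rest_s + profile$total_s
  n <- round(total * fs_kin)
  t <- seq_len(n) / fs_kin
  u <- t - lead_rest_s  # time since movement onset

  pos_fun <- if (ramp == "linear") trapezoid_position else minjerk_position
  x <- matrix(0, nrow = n, ncol = 3)
  x[, dof] <- dir * pos_fun(u, profile)

  phase <- rep("rest", n)
  phase[u > 0 & u <= profile$rise_s] <- "rise"
  phase[u > profile$rise_s & u <= profile$rise_s + profile$hold_s] <- "hold"
  phase[u > profile$rise_s + profile$hold_s & u <= profile$total_s] <- "fall"

  active <- rep(NA_integer_, n)
  active[phase != "rest"] <- dof
  mv_id <- match_movement_id(dof, dir)
  active_mv <- rep(NA_integer_, n)
  active_mv[phase != "rest"] <- mv_id

  out <- list(
    t = t, x = x, active_dof = active, active_movement = active_mv,
    phase = phase,
    trial_id = rep(1L, n), block_id = rep(1L, n),
    fs = fs_kin, speed = profile$name
  )
  class(out) <- "kin_trajectory"
  out
}

match_movement_id <- function(dof, direction) {
  mv <- movement_specs()
  mv$movement[mv$dof == dof & mv$direction == direction]
}

#' Generate a full training session of trials
#'
#' Concatenates `n_trials_per_movement` trials of each of the six movements
#' at one speed, in a seed-determined pseudorandom order, separated by
#' `rest_s` of rest. Each trial block (its leading rest plus the movement)
#' carries a `trial_id`/`block_id` label so folds can select whole trials.
#'
#' @param speed speed name (`"slow"`, `"medium"`, `"fast"`).
#' @param n_trials_per_movement trials of each movement (a full offline
#'   training dataset uses 20).
#' @param rest_s rest between trials, seconds (default 2).
#' @param fs_kin kinematic rate in Hz.
#' @param seed integer seed controlling the trial order.
#' @param ramp ramp shape, see [generate_trial_trajectory()].
#' @return a `kin_trajectory` whose attribute `trial_table` is a data.frame
#'   (trial_id, movement, dof, direction, speed).
#' @export
generate_session <- function(speed, n_trials_per_movement = 20, rest_s = 2,
                             fs_kin = 30, seed = 1,
                             ramp = c("linear", "minjerk")) {
  stopifnot(n_trials_per_movement >= 1)
  ramp <- match.arg(ramp)
  profile <- make_speed_profile(speed)
  mv <- movement_specs()

  set.seed(derive_seed(seed, 0L))
  order <- sample(rep(mv$movement, n_trials_per_movement))

  pieces <- vector("list", length(order))
  for (k in seq_along(order)) {
    m <- mv[mv$movement == order[k], ]
    tr <- generate_trial_trajectory(profile, m, fs_kin = fs_kin,
                                    lead_rest_s = rest_s, ramp = ramp)
    tr$trial_id <- rep(k, length(tr$t))
    tr$block_id <- rep(k, length(tr$t))
    pieces[[k]] <- tr
  }

  n_each <- vapply(pieces, function(p) length(p$t), integer(1))
  out <- list(
    t = seq_len(sum(n_each)) / fs_kin,
    x = do.call(rbind, lapply(pieces, `[[`, "x")),
    active_dof = unlist(lapply(pieces, `[[`, "active_dof")),
    active_movement = unlist(lapply(pieces, `[[`, "active_movement")),
    phase = unlist(lapply(pieces, `[[`, "phase")),
    trial_id = unlist(lapply(pieces, `[[`, "trial_id")),
    block_id = unlist(lapply(pieces, `[[`, "block_id")),
    fs = fs_kin, speed = speed
  )
  class(out) <- "kin_trajectory"
  attr(out, "trial_table") <- data.frame(
    trial_id = seq_along(order),
    movement = order,
    dof = mv$dof[match(order, mv$movement)],
    direction = mv$direction[match(order, mv$movement)],
    speed = speed,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  out
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat(sprintf("<kin_trajectory: %d samples @ %g Hz (%.1f s), speed '%s', %d trial(s)>\n",
              length(x$t), x$fs, length(x$t) / x$fs, x$speed %||% "?",
              length(unique(stats::na.omit(x$trial_id)))))
  invisible(x)
}
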