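#' Fit a Kalman-filter continuous decoder
#'
#' Fits the linear-Gaussian state-space model used for continuous myoelectric
#' decoding: a first-order autoregressive state model
#' `x_t = A x_{t-1} + w_t`, `w ~ N(0, W)` over the kinematic state (positions
#' of the d DOFs), and a linear observation model
#' `z_t = H x_t + q_t`, `q ~ N(0, Q)` mapping kinematics to the (centered)
#' feature vector. `A` is the least-squares transition fit, `W` its residual
#' covariance, `H` a ridge-regularized regression of the centered features on
#' the kinematics, and `Q` the residual covariance of that fit. Features are
#' centered because resting EMG has a nonzero MAV floor that would otherwise
#' bias predictions at rest.
#'
#' @param Z features, frames x p matrix.
#' @param X kinematics, frames x d matrix.
#' @param ridge_lambda ridge weight for the observation fit; default
#'   `1e-3 * trace(X'X) / d` (trace-normalized), which conditions the fit
#'   when p (528) is large relative to the session length.
#' @param blocks optional integer vector (length = frames) of contiguous-block
#'   ids; state transitions across block seams (non-adjacent trials) are
#'   excluded from the fit of `A` and `W`.
#' @return an object of class `kalman_model` with fields `A`, `W`, `H`, `Q`,
#'   `ridge_lambda`, `feature_mean`, `d`, `p`.
#' @export
fit_kalman <- function(Z, X, ridge_lambda = NULL, blocks = NULL) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  stopifnot(nrow(Z) == nrow(X), nrow(X) >= 2)
  T_ <- nrow(X); d <- ncol(X); p <- ncol(Z)

  v <- apply(X, 2, var)
  if (any(v <= 0)) {
    stop("degenerate kinematics: zero variance in DOF ",
         paste(which(v <= 0), collapse = ", "))
  }

  # state model on within-block transitions
  idx <- seq_len(T_ - 1L)
  if (!is.null(blocks)) idx <- idx[blocks[idx] == blocks[idx + 1L]]
  X1 <- X[idx, , drop = FALSE]; X2 <- X[idx + 1L, , drop = FALSE]
  A <- t(solve(crossprod(X1), crossprod(X1, X2)))
  resA <- X2 - X1 %*% t(A)
  W <- crossprod(resA) / nrow(resA)
  W <- (W + t(W)) / 2

  # observation model: ridge regression of centered features on centered
  # kinematics; the stored feature_mean is the full observation offset
  # (mean(Z) - H mean(X)), so z - feature_mean = H x at the fitted optimum
  z_mean <- colMeans(Z)
  x_mean <- colMeans(X)
  Zc <- sweep(Z, 2, z_mean)
  Xc <- sweep(X, 2, x_mean)
  if (is.null(ridge_lambda)) ridge_lambda <- 1e-3 * sum(Xc^2) / d
  G <- crossprod(Xc) + diag(ridge_lambda, d)
  H <- t(solve(G, crossprod(Xc, Zc)))          # p x d
  resH <- Zc - Xc %*% t(H)
  Q <- crossprod(resH) / T_
  Q <- (Q + t(Q)) / 2
  feature_mean <- as.numeric(z_mean - H %*% x_mean)

  out <- list(A = A, W = W, H = H, Q = Q, ridge_lambda = ridge_lambda,
              feature_mean = feature_mean, d = d, p = p)
  class(out) <- "kalman_model"
  out
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model: d = %d state DOFs, p = %d features, ridge = %.3g>\n",
              x$d, x$p, x$ridge_lambda))
  invisible(x)
}

#' One predict/update step of the Kalman filter
#'
#' Standard covariance-form recursion: predict `x- = A x`, `P- = A P A' + W`,
#' then update with gain `K = P- H' (H P- H' + Q)^-1`,
#' `x+ = x- + K (z_c - H x-)`, `P+ = (I - K H) P-`. The observation is
#' centered with the model's stored feature mean. `P` is symmetrized after
#' the update.
#'
#' @param model a [fit_kalman()] model.
#' @param state list with `x` (d-vector) and `P` (d x d covariance).
#' @param z raw p-vector of features for this frame.
#' @return updated state list with fields `x` and `P`.
#' @export
kalman_step <- function(model, state, z) {
  stopifnot(length(state$x) == model$d, length(z) == model$p)
  A <- model$A; W <- model$W; H <- model$H; Q <- model$Q
  zc <- as.numeric(z) - model$feature_mean
  x_pred <- A %*% state$x
  P_pred <- A %*% state$P %*% t(A) + W
  S <- H %*% P_pred %*% t(H) + Q
  K <- tryCatch(
    t(solve(S, H %*% P_pred)),
    error = function(e) stop("innovation covariance is not invertible; ",
                             "increase ridge_lambda or add jitter to Q")
  )
  x_new <- x_pred + K %*% (zc - H %*% x_pred)
  P_new <- (diag(model$d) - K %*% H) %*% P_pred
  P_new <- (P_new + t(P_new)) / 2
  list(x = as.numeric(x_new), P = P_new)
}

# Precompute the information-form quantities: with Qi = Q^-1 (jittered
# Cholesky inverse), the update is P+ = (P-^-1 + H'QiH)^-1 and
# x+ = x- + P+ (H'Qi z_c - H'QiH x-). Algebraically identical to the
# covariance form but needs only d x d solves per frame once
# G z_c = H'Qi z_c is precomputed for all frames in one BLAS call.
kalman_precompute <- function(model, jitter = 1e-8) {
  Qj <- model$Q + diag(jitter * mean(diag(model$Q)) + 1e-300, model$p)
  R <- tryCatch(chol(Qj), error = function(e)
    stop("observation covariance is not positive definite; ",
         "increase ridge_lambda or jitter"))
  Qi <- chol2inv(R)
  Gt <- Qi %*% model$H            # p x d
  M <- t(model$H) %*% Gt          # d x d
  list(Gt = Gt, M = (M + t(M)) / 2)
}

#' Run the Kalman filter over a feature sequence
#'
#' Iterates the filter from `x0 = 0`, `P0 = W` over all frames. Uses an
#' algebraically equivalent information-form update (the p x p innovation
#' inverse is precomputed once through a jittered Cholesky factor of `Q`).
#' With `steady_state = TRUE` the error covariance is first iterated to
#' convergence and the resulting fixed gain is used for every frame, which
#' matches the iterated gain to well below 1e-6 after convergence.
#'
#' @param model a [fit_kalman()] model.
#' @param Z frames x p feature matrix.
#' @param steady_state use the precomputed steady-state gain (default FALSE).
#' @param jitter relative jitter added to `Q` before inversion (default 1e-8).
#' @return frames x d matrix of predicted kinematics.
#' @export
run_kalman <- function(model, Z, steady_state = FALSE, jitter = 1e-8) {
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) == model$p)
  T_ <- nrow(Z); d <- model$d
  pre <- kalman_precompute(model, jitter)
  Zc <- sweep(Z, 2, model$feature_mean)
  GZ <- Zc %*% pre$Gt             # frames x d: H'Qi z_c per frame
  A <- model$A; W <- model$W; M <- pre$M

  X_hat <- matrix(0, T_, d)
  x <- rep(0, d); P <- W

  if (steady_state) {
    for (i in 1:10000) {
      P_pred <- A %*% P %*% t(A) + W
      P_new <- solve(solve(P_pred) + M)
      P_new <- (P_new + t(P_new)) / 2
      if (max(abs(P_new - P)) < 1e-14) { P <- P_new; break }
      P <- P_new
    }
    P_pred <- A %*% P %*% t(A) + W
    Pp <- solve(solve(P_pred) + M)
    for (t in seq_len(T_)) {
      x_pred <- A %*% x
      x <- x_pred + Pp %*% (GZ[t, ] - M %*% x_pred)
      X_hat[t, ] <- x
    }
  } else {
    for (t in seq_len(T_)) {
      x_pred <- A %*% x
      P_pred <- A %*% P %*% t(A) + W
      Pp <- solve(solve(P_pred) + M)
      Pp <- (Pp + t(Pp)) / 2
      x <- x_pred + Pp %*% (GZ[t, ] - M %*% x_pred)
      P <- Pp
      X_hat[t, ] <- x
    }
  }
  X_hat
}

#' Threshold/rescale post-processing of the modified Kalman filter
#'
#' Per DOF, predictions whose magnitude is at or below `threshold` (a
#' fraction of the 0-to-1 span of each direction) are set to zero and the
#' remainder is linearly rescaled to span the full range:
#' `sign(x) * (|x| - threshold) / (1 - threshold)`. The map is continuous,
#' odd, monotone nondecreasing and fixes +/-1.
#'
#' @param x numeric vector or matrix of kinematic predictions in [-1, 1].
#' @param threshold dead-zone fraction in [0, 1) (default 0.2).
#' @param rescale if FALSE, supra-threshold values pass through unchanged
#'   instead of being rescaled.
#' @return object of the same shape as `x`.
#' @export
apply_mkf_threshold <- function(x, threshold = 0.2, rescale = TRUE) {
  stopifnot(threshold >= 0, threshold < 1)
  ax <- abs(x)
  out <- if (rescale) sign(x) * (ax - threshold) / (1 - threshold) else x
  out[ax <= threshold] <- 0
  out
}
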