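# Independent oracles used by the decoder tests. These share no code with
# the package implementation: the Kalman oracle conditions the explicit
# joint Gaussian of (state, observation) at every step.

# Brute-force Bayesian recursion for the linear-Gaussian state-space model.
# Z: T x p observations (already centered), returns T x d posterior means.
oracle_kalman <- function(A, W, H, Q, Z, x0, P0) {
  d <- nrow(A)
  x <- x0
  P <- P0
  out <- matrix(0, nrow(Z), d)
  for (t in seq_len(nrow(Z))) {
    # prior after dynamics
    m_prior <- A %*% x
    S_prior <- A %*% P %*% t(A) + W
    # joint Gaussian of (x_t, z_t):
    #   mean (m_prior, H m_prior)
    #   cov  [S, S H'; H S, H S H' + Q]
    cross <- S_prior %*% t(H)
    S_zz <- H %*% S_prior %*% t(H) + Q
    gain <- t(solve(S_zz, t(cross)))          # S H' (HSH'+Q)^-1
    x <- m_prior + gain %*% (Z[t, ] - H %*% m_prior)
    P <- S_prior - gain %*% t(cross)
    P <- (P + t(P)) / 2
    out[t, ] <- x
  }
  out
}

# Draw a random small state-space instance and a trajectory from it.
random_kalman_instance <- function(seed, d_max = 2, p_max = 3, T_max = 50) {
  set.seed(seed)
  d <- sample(d_max, 1)
  p <- sample(p_max, 1)
  T_ <- sample(10:T_max, 1)
  A <- diag(runif(d, 0.5, 0.95), d)
  A <- A + matrix(rnorm(d * d, 0, 0.05), d)
  Wc <- matrix(rnorm(d * d), d)
  W <- crossprod(Wc) / d + diag(0.1, d)
  H <- matrix(rnorm(p * d), p, d)
  Qc <- matrix(rnorm(p * p), p)
  Q <- crossprod(Qc) / p + diag(0.1, p)
  X <- matrix(0, T_, d)
  Z <- matrix(0, T_, p)
  x <- rnorm(d)
  for (t in seq_len(T_)) {
    x <- as.numeric(A %*% x) + as.numeric(chol(W) %*% rnorm(d))
    X[t, ] <- x
    Z[t, ] <- as.numeric(H %*% x) + as.numeric(chol(Q) %*% rnorm(p))
  }
  list(A = A, W = W, H = H, Q = Q, X = X, Z = Z, d = d, p = p, T_ = T_)
}
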