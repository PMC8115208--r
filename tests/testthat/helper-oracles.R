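# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementation.

# Moore-Penrose pseudo-inverse least squares (SVD route)
pinv_lsq <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(s$d) * 1e-12
  as.vector(s$v[, keep, drop = FALSE] %*%
              ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

# closed-form solution of x'' = omega^2 x - c x' (relative coordinates),
# evaluated at times tt from initial state (x0, v0)
lip_closed_form <- function(x0, v0, tt, omega, c_damp = 0) {
  disc <- sqrt(c_damp^2 + 4 * omega^2)
  s1 <- (-c_damp + disc) / 2
  s2 <- (-c_damp - disc) / 2
  A <- (v0 - s2 * x0) / (s1 - s2)
  B <- (s1 * x0 - v0) / (s1 - s2)
  cbind(x = A * exp(s1 * tt) + B * exp(s2 * tt),
        v = A * s1 * exp(s1 * tt) + B * s2 * exp(s2 * tt))
}

# smooth unit-variance Gaussian fields via direct kernel-matrix smoothing
# (independent construction of the null fields used in Monte-Carlo checks)
gen_fields_oracle <- function(n, n_nodes, fwhm, pad = ceiling(3 * fwhm)) {
  if (fwhm <= 0) return(matrix(rnorm(n * n_nodes), n, n_nodes))
  sigma <- fwhm / sqrt(8 * log(2))
  wide <- n_nodes + 2 * pad
  K <- outer(seq_len(n_nodes) + pad, seq_len(wide),
             function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K <- K / sqrt(rowSums(K^2))
  matrix(rnorm(n * wide), n, wide) %*% t(K)
}

# small synthetic marker set: 3 markers on analytic trajectories
toy_marker_set <- function(n = 10, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  mk <- function(f) cbind(x = sin(2 * pi * f * t), y = cos(2 * pi * f * t),
                          z = t * f)
  marker_set(list(M1 = mk(1), M2 = mk(2), M3 = mk(3)), rate_hz = rate)
}

# full-pipeline regression series for one simulated trial
trial_series <- function(trial, labels = c(left = "control",
                                           right = "control"),
                         filter = NULL) {
  a <- analyze_trial(trial, labels, filter = filter)
  fit_series(a$design$com_x, a$design$com_v, a$design$fp)
}

# stationary step-width SD implied by the placement law with placement
# noise only (discrete Lyapunov equation of the linearized return map)
analytic_width_sd <- function(cfg) {
  omega <- cfg$omega
  T <- cfg$step_duration
  C <- cosh(omega * T); S <- sinh(omega * T)
  M <- matrix(c(C, S / omega, omega * S, C), 2, 2, byrow = TRUE)
  f <- cfg$control_node_pct / 100
  Mf <- matrix(c(cosh(omega * T * f), sinh(omega * T * f) / omega,
                 omega * sinh(omega * T * f), cosh(omega * T * f)),
               2, 2, byrow = TRUE)
  g <- c(cfg$gain_pos, cfg$gain_vel) %*% Mf
  J <- rbind(g - M[1, ], -M[2, ])
  s2 <- cfg$placement_noise_sd^2
  Q <- matrix(0, 2, 2); Q[1, 1] <- s2
  Sig <- matrix(solve(diag(4) - kronecker(J, J), as.vector(Q)), 2, 2)
  sqrt(as.numeric(g %*% Sig %*% t(g)) + s2)
}
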