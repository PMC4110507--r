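# Independent oracles used across the suite.

# Angular velocity from quaternion calculus: omega = 2 * qdot (x) q*, with
# qdot by central differences on the quaternion components. Independent of
# the rotation-matrix route used by poisson_angular_velocity().
quat_derivative_omega <- function(q, dt) {
  n <- nrow(q)
  qdot <- matrix(0, n, 4)
  qdot[1, ] <- (q[2, ] - q[1, ]) / dt
  qdot[n, ] <- (q[n, ] - q[n - 1, ]) / dt
  if (n > 2) qdot[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) / (2 * dt)
  w <- 2 * quat_multiply(qdot, quat_conjugate(q))
  w[, 2:4]
}

# Closed-form magnitude of the g-h filter's error (tremor) transfer function
# at frequency f for sample rate `rate`: from the z-transform of the
# recursion, E/Y = d^2 / (d^2 + z^-1 (g d + h)) with d = 1 - z^-1.
gh_error_response <- function(theta, f, rate) {
  g <- 1 - theta^2
  h <- (1 - theta)^2
  z <- exp(1i * 2 * pi * f / rate)
  d <- 1 - 1 / z
  Mod(d^2 / (d^2 + (1 / z) * (g * d + h)))
}

# steady-state amplitude of a sinusoidal component at frequency f,
# estimated by quadrature demodulation over the window where keep is TRUE
sine_amplitude <- function(x, t, f, keep = rep(TRUE, length(x))) {
  x <- x[keep]; t <- t[keep]
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}

# smooth seeded quaternion path built from sinusoidal Euler angles -- a
# construction independent of integrate_orientation()
random_smooth_quat_path <- function(seed, t) {
  set.seed(seed)
  a <- runif(3, 0.2, 0.8); f <- runif(3, 0.2, 1.2); p <- runif(3, 0, 2 * pi)
  n <- length(t)
  R <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    R[, , i] <- euler_to_matrix(a[1] * sin(2 * pi * f[1] * t[i] + p[1]),
                                a[2] * sin(2 * pi * f[2] * t[i] + p[2]),
                                a[3] * sin(2 * pi * f[3] * t[i] + p[3]))
  }
  matrix_to_quat(R)
}

# small deterministic instance table: `per_class` instances per chain
# ordinal, rank predictors a fixed permutation per class (separable)
separable_rank_table <- function(per_class = 15, n_classes = 3) {
  perms <- lapply(seq_len(n_classes), function(j) {
    ((seq_len(n_classes) + j - 2) %% n_classes) + 1
  })
  rows <- purrr::map_dfr(seq_len(n_classes), function(j) {
    ranks <- as.list(stats::setNames(rep(perms[[j]], length.out = 18),
                                     paste0("f", 1:18)))
    dplyr::bind_cols(tibble::as_tibble(ranks),
                     tibble::tibble(location = factor(j)))
  })
  rows[rep(seq_len(nrow(rows)), each = per_class), ]
}

# short synthetic trial for fast unit tests (10 s, one cycle: keeps the
# 0.1 Hz fundamental of the default protocol)
quick_config <- function(seed, ...) {
  synth_config(duration = 10, n_cycles = 1, seed = seed, ...)
}

rms <- function(x) sqrt(mean(x^2))
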