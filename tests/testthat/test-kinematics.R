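test_that("static orientation yields zero angular velocity", {
  t <- seq(0, 1, by = 0.01)
  q <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  w <- poisson_angular_velocity(orientation_trace(t, q))
  expect_equal(max(abs(as.matrix(w[, c("wx", "wy", "wz")]))), 0)
})

test_that("constant-rate rotations about each axis are recovered", {
  t <- seq(0, 2, by = 0.01)
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    q <- cbind(cos(t / 2), outer(sin(t / 2), axis))  # 1 rad/s about axis
    w <- poisson_angular_velocity(orientation_trace(t, q))
    om <- as.matrix(w[, c("wx", "wy", "wz")])
    interior <- 2:(length(t) - 1)
    err <- sweep(om[interior, ], 2, axis)
    expect_lt(max(abs(err)), 1e-3)
  }
})

test_that("Poisson extraction agrees with the quaternion-derivative oracle", {
  t <- seq(0, 3, by = 0.01)
  for (seed in 1:10) {
    q <- random_smooth_quat_path(seed, t)
    w <- poisson_angular_velocity(orientation_trace(t, q))
    w_oracle <- quat_derivative_omega(q, 0.01)
    err <- as.matrix(w[, c("wx", "wy", "wz")]) - w_oracle
    expect_lt(sqrt(mean(err^2)), 1e-3)
  }
})

test_that("short traces are rejected", {
  t <- c(0, 0.01)
  q <- matrix(rep(c(1, 0, 0, 0), 2), ncol = 4, byrow = TRUE)
  expect_error(poisson_angular_velocity(orientation_trace(t, q)),
               "at least 3 samples")
})

test_that("global-frame output is equivariant under a fixed frame rotation", {
  t <- seq(0, 2, by = 0.01)
  q <- random_smooth_quat_path(42, t)
  Q <- axis_angle_matrix(c(1, 2, 0.5), 1.1)
  R <- quat_to_matrix(q)
  R2 <- array(0, dim = dim(R))
  for (i in seq_len(dim(R)[3])) R2[, , i] <- Q %*% R[, , i]
  w1 <- tremorkin:::omega_matrix(poisson_angular_velocity(orientation_trace(t, q)))
  w2 <- tremorkin:::omega_matrix(poisson_angular_velocity(
    orientation_trace(t, matrix_to_quat(R2))))
  expect_equal(w2, w1 %*% t(Q), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("orientation integration and Poisson extraction are inverse for band-limited motion", {
  set.seed(7)
  t <- seq(0, 10, by = 0.01)
  for (k in 1:5) {
    amp <- runif(3, 2, 10 / sqrt(3))
    f <- runif(3, 0.2, 1)
    ph <- runif(3, 0, 2 * pi)
    om <- sapply(1:3, function(i) amp[i] * sin(2 * pi * f[i] * t + ph[i]))
    rec <- poisson_angular_velocity(integrate_orientation(angvel_trace(t, om)))
    err <- tremorkin:::omega_matrix(rec) - om
    expect_lt(sqrt(mean(err^2)), 1e-2)
  }
})

test_that("Euler decomposition handles single-axis rotations and round trips", {
  t <- seq(0, 0.1, by = 0.01)
  q <- matrix(rep(c(cos(0.15), 0, 0, sin(0.15)), length(t)),
              ncol = 4, byrow = TRUE)  # fixed 0.3 rad about z
  e <- euler_decompose(orientation_trace(t, q))
  expect_equal(e$yaw, rep(0.3, length(t)), tolerance = 1e-12)
  expect_equal(e$pitch, rep(0, length(t)), tolerance = 1e-12)
  expect_equal(e$roll, rep(0, length(t)), tolerance = 1e-12)

  qi <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  ei <- euler_decompose(orientation_trace(t, qi))
  expect_true(all(as.matrix(ei[, c("yaw", "pitch", "roll")]) == 0))

  set.seed(11)
  for (i in 1:1000) {
    ang <- c(runif(1, -pi, pi), runif(1, -1.4, 1.4), runif(1, -pi, pi))
    R <- euler_to_matrix(ang[1], ang[2], ang[3])
    e1 <- euler_decompose(orientation_trace(
      c(0, 0.01, 0.02), matrix_to_quat(array(rep(R, 3), c(3, 3, 3)))))
    back <- c(e1$yaw[1], e1$pitch[1], e1$roll[1])
    expect_lt(max(abs(back - ang)), 1e-9)
  }
})

test_that("unwrapping removes 2*pi jumps from continuous rotations", {
  t <- seq(0, 8, by = 0.01)
  q <- cbind(cos(t), 0, 0, sin(t))  # 2 rad/s about z: yaw exceeds pi
  e <- euler_decompose(orientation_trace(t, q))
  expect_lt(max(abs(diff(e$yaw))), 0.1)
  expect_equal(e$yaw[length(t)], 16, tolerance = 1e-6)
})

test_that("joint angular velocity subtracts element-wise and validates inputs", {
  t <- seq(0, 1, by = 0.01)
  om <- cbind(sin(t), cos(t), t)
  a <- angvel_trace(t, om)
  b <- angvel_trace(t, om * 0.4)
  d <- joint_angular_velocity(a, b)
  expect_equal(tremorkin:::omega_matrix(d), om * 0.6, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tremorkin:::omega_matrix(joint_angular_velocity(a, a)),
               matrix(0, length(t), 3), ignore_attr = TRUE)
  zero <- angvel_trace(t, matrix(0, length(t), 3))
  expect_equal(tremorkin:::omega_matrix(joint_angular_velocity(a, zero)), om,
               ignore_attr = TRUE)
  shifted <- angvel_trace(t + 0.5, om)
  expect_error(joint_angular_velocity(a, shifted), "timestamps")
})

test_that("angular displacement integrates closed forms and is additive", {
  t <- seq(0, 2, by = 0.01)
  const <- angvel_trace(t, cbind(0, 0, rep(1, length(t))))
  d <- angular_displacement(const)
  expect_equal(d$z[length(t)], 2, tolerance = 1e-12)
  expect_equal(d$z, t, tolerance = 1e-12)
  expect_true(all(d$x == 0) && all(d$y == 0))

  osc <- angvel_trace(t, cbind(cos(2 * pi * t), 0, 0))
  dosc <- angular_displacement(osc)
  expect_lt(max(abs(dosc$x - sin(2 * pi * t) / (2 * pi))), 1e-4)

  # additivity over concatenated segments
  cut <- 101
  first <- angular_displacement(angvel_trace(t[1:cut],
                                             cbind(cos(2 * pi * t[1:cut]), 0, 0)))
  second <- angular_displacement(angvel_trace(t[cut:length(t)],
                                              cbind(cos(2 * pi * t[cut:length(t)]), 0, 0)))
  expect_equal(dosc$x[length(t)],
               first$x[cut] + second$x[nrow(second)], tolerance = 1e-12)
})

test_that("angular acceleration differentiates closed forms", {
  t <- seq(0, 2, by = 0.01)
  expect_true(all(as.matrix(angular_acceleration(
    angvel_trace(t, cbind(1, 1, 1) [rep(1, length(t)), ]))[, c("x", "y", "z")]) == 0))

  ramp <- angvel_trace(t, cbind(0, 0, t))
  acc <- angular_acceleration(ramp)
  expect_lt(max(abs(acc$z[2:(length(t) - 1)] - 1)), 1e-10)

  osc <- angvel_trace(t, cbind(sin(2 * pi * t), 0, 0))
  acc2 <- angular_acceleration(osc)
  ref <- 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  rel <- sqrt(mean((acc2$x[interior] - ref[interior])^2)) / sqrt(mean(ref^2))
  expect_lt(rel, 0.005)
})

test_that("resampling is exact on constants and linear ramps, bounded on sines", {
  t <- seq(0, 1, by = 0.01)
  const <- resample_series(tibble::tibble(t = t, v = rep(3, length(t))), 1000)
  expect_true(all(const$v == 3))
  ramp <- resample_series(tibble::tibble(t = t, v = 2 * t + 1), 1000)
  expect_equal(ramp$v, 2 * ramp$t + 1, tolerance = 1e-12)

  sine <- tibble::tibble(t = t, v = sin(2 * pi * 5 * t))
  up <- resample_series(sine, 1000)
  bound <- (2 * pi * 5 * 0.01)^2 / 8
  expect_lt(max(abs(up$v - sin(2 * pi * 5 * up$t))), bound)

  expect_error(resample_series(sine, 50), "downsampling")
})
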