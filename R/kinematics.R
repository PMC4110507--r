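#' Angular velocity from an orientation trace (Poisson equation)
#'
#' Differentiates a rigid-body orientation series into angular velocity using
#' the Poisson kinematic relation: the skew-symmetric angular-velocity matrix
#' of a rotating frame is \eqn{\Omega = \dot{R} R^{-1}} in the global
#' (spatial) frame, or \eqn{R^{-1}\dot{R}} in the body frame. Finite angular
#' displacements do not add like vectors, so attitude angles cannot simply be
#' differentiated component-wise; this route is exact in the limit of small
#' time steps. \eqn{\dot{R}} is estimated by central differences (one-sided
#' at the endpoints) and \eqn{\Omega} is skew-symmetrized as
#' \eqn{(\Omega - \Omega^{T})/2} before reading off the components
#' \eqn{\omega = (\Omega_{32}, \Omega_{13}, \Omega_{21})}.
#'
#' @param trace an [orientation_trace()] with at least 3 samples.
#' @param frame `"global"` for \eqn{\dot{R}R^{-1}} (default) or `"body"` for
#'   \eqn{R^{-1}\dot{R}}.
#' @return an [angvel_trace()] with the same timestamps, in rad/s.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' q <- cbind(cos(t / 2), 0, 0, sin(t / 2))  # 1 rad/s about z
#' w <- poisson_angular_velocity(orientation_trace(t, q))
#' colMeans(as.matrix(w[, c("wx", "wy", "wz")]))
#' @export
poisson_angular_velocity <- function(trace, frame = c("global", "body")) {
  frame <- match.arg(frame)
  if (nrow(trace) < 3) {
    stop_tremorkin("orientation trace must have at least 3 samples")
  }
  R <- as_rotation_array(trace)
  n <- dim(R)[3]
  dt <- trace_dt(trace)
  Rdot <- array(0, dim = dim(R))
  Rdot[, , 1] <- (R[, , 2] - R[, , 1]) / dt
  Rdot[, , n] <- (R[, , n] - R[, , n - 1]) / dt
  if (n > 2) {
    idx <- 2:(n - 1)
    Rdot[, , idx] <- (R[, , idx + 1, drop = FALSE] -
                        R[, , idx - 1, drop = FALSE]) / (2 * dt)
  }
  omega <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Om <- if (frame == "global") {
      Rdot[, , i] %*% t(R[, , i])
    } else {
      t(R[, , i]) %*% Rdot[, , i]
    }
    Om <- (Om - t(Om)) / 2
    omega[i, ] <- c(Om[3, 2], Om[1, 3], Om[2, 1])
  }
  angvel_trace(trace$t, omega, frame = frame)
}

#' Euler-angle decomposition of an orientation trace
#'
#' Extracts per-sample intrinsic Euler angles in the given axis convention
#' (default Z-Y-X: yaw, pitch, roll) and unwraps each angle series over time
#' so no consecutive samples jump by 2*pi. Samples within `lock_tol` of
#' gimbal lock (|pitch| near pi/2 for Z-Y-X) trigger a warning but the
#' decomposition is still returned.
#'
#' @param trace an [orientation_trace()].
#' @param convention axis order; currently `"zyx"` (yaw-pitch-roll).
#' @param lock_tol proximity of the pitch to +/- pi/2 (radians) that counts
#'   as gimbal lock (default 1e-3).
#' @return tibble with columns `t`, `yaw`, `pitch`, `roll` (radians).
#' @export
euler_decompose <- function(trace, convention = "zyx", lock_tol = 1e-3) {
  convention <- match.arg(convention, "zyx")
  R <- as_rotation_array(trace)
  n <- dim(R)[3]
  yaw <- pitch <- roll <- numeric(n)
  locked <- FALSE
  for (i in seq_len(n)) {
    m <- R[, , i]
    sp <- -m[3, 1]
    sp <- max(-1, min(1, sp))
    pitch[i] <- asin(sp)
    if (abs(abs(sp) - 1) < lock_tol) {
      locked <- TRUE
      yaw[i] <- atan2(-m[1, 2], m[2, 2])
      roll[i] <- 0
    } else {
      yaw[i] <- atan2(m[2, 1], m[1, 1])
      roll[i] <- atan2(m[3, 2], m[3, 3])
    }
  }
  if (locked) {
    rlang::warn("pitch within tolerance of gimbal lock; roll folded into yaw at locked samples")
  }
  tibble::tibble(t = trace$t,
                 yaw = unwrap_angle(yaw),
                 pitch = unwrap_angle(pitch),
                 roll = unwrap_angle(roll))
}

#' @rdname euler_decompose
#' @param yaw,pitch,roll Euler angles in radians (Z-Y-X convention).
#' @return `euler_to_matrix()` returns the 3x3 rotation matrix
#'   `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`.
#' @export
euler_to_matrix <- function(yaw, pitch, roll) {
  axis_angle_matrix(c(0, 0, 1), yaw) %*%
    axis_angle_matrix(c(0, 1, 0), pitch) %*%
    axis_angle_matrix(c(1, 0, 0), roll)
}

unwrap_angle <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Joint angular velocity by proximal-distal subtraction
#'
#' The angular velocity of the joint between two instrumented segments is the
#' element-wise difference of the distal and proximal sensors' angular
#' velocities, both expressed in the same frame.
#'
#' @param distal,proximal [angvel_trace()] objects with identical timestamps
#'   and frames.
#' @return an [angvel_trace()] of `distal - proximal`.
#' @export
joint_angular_velocity <- function(distal, proximal) {
  if (nrow(distal) != nrow(proximal) ||
      max(abs(distal$t - proximal$t)) > 1e-9) {
    stop_tremorkin("distal and proximal traces must share timestamps")
  }
  if (!identical(attr(distal, "frame"), attr(proximal, "frame"))) {
    stop_tremorkin("distal and proximal traces must share the frame tag")
  }
  new_angvel_like(distal, omega_matrix(distal) - omega_matrix(proximal))
}

#' Angular displacement and acceleration of an angular-velocity trace
#'
#' `angular_displacement()` integrates each axis with the cumulative
#' trapezoidal rule, starting at zero; `angular_acceleration()`
#' differentiates each axis with central differences (one-sided at the
#' endpoints).
#'
#' @param av an [angvel_trace()].
#' @return a tibble `t, x, y, z` of per-axis angle (rad) or angular
#'   acceleration (rad/s^2).
#' @export
angular_displacement <- function(av) {
  om <- omega_matrix(av)
  dt <- trace_dt(av)
  disp <- apply(om, 2, function(w) {
    c(0, cumsum((head(w, -1) + tail(w, -1)) / 2 * dt))
  })
  tibble::tibble(t = av$t, x = disp[, 1], y = disp[, 2], z = disp[, 3])
}

#' @rdname angular_displacement
#' @export
angular_acceleration <- function(av) {
  if (nrow(av) < 3) {
    stop_tremorkin("angular-velocity trace must have at least 3 samples")
  }
  om <- omega_matrix(av)
  dt <- trace_dt(av)
  n <- nrow(om)
  acc <- matrix(0, n, 3)
  acc[1, ] <- (om[2, ] - om[1, ]) / dt
  acc[n, ] <- (om[n, ] - om[n - 1, ]) / dt
  if (n > 2) {
    acc[2:(n - 1), ] <- (om[3:n, ] - om[1:(n - 2), ]) / (2 * dt)
  }
  tibble::tibble(t = av$t, x = acc[, 1], y = acc[, 2], z = acc[, 3])
}

#' Resample a uniformly sampled series to a higher rate
#'
#' Linear interpolation onto a uniform grid at `target_rate` spanning the
#' same time interval. Only upsampling is supported: the downstream tracking
#' filter runs at 1 kHz on 100 Hz recordings.
#'
#' @param series a tibble whose first column is `t` (uniform) and whose
#'   remaining numeric columns are signals, e.g. an [angvel_trace()].
#' @param target_rate target sampling rate in Hz, at least the source rate.
#' @return a tibble of the same shape on the new grid; `angvel_trace` class
#'   and frame are preserved when the input is one.
#' @export
resample_series <- function(series, target_rate) {
  src_rate <- 1 / mean(diff(series$t))
  if (target_rate < src_rate * (1 - 1e-9)) {
    stop_tremorkin(sprintf(
      "downsampling not supported (source %.6g Hz, target %.6g Hz)",
      src_rate, target_rate))
  }
  t_new <- seq(series$t[1], series$t[nrow(series)], by = 1 / target_rate)
  cols <- setdiff(names(series), "t")
  out <- tibble::as_tibble(c(
    list(t = t_new),
    lapply(series[cols], function(v) approx(series$t, v, xout = t_new)$y)
  ))
  if (inherits(series, "angvel_trace")) {
    out <- angvel_trace(t_new, as.matrix(out[, c("wx", "wy", "wz")]),
                        frame = attr(series, "frame"))
  }
  out
}

#' Integrate an angular-velocity series into an orientation trace
#'
#' Advances the orientation with exact per-step axis-angle increments
#' (matrix exponential of the skew of the midpoint angular velocity), so the
#' Poisson-equation round trip is a genuine inverse up to differentiation
#' error rather than a shared small-angle approximation.
#'
#' @param av an [angvel_trace()] in the global frame.
#' @param R0 initial 3x3 orientation (default identity).
#' @return an [orientation_trace()].
#' @export
integrate_orientation <- function(av, R0 = diag(3)) {
  om <- omega_matrix(av)
  n <- nrow(om)
  dt <- trace_dt(av)
  R <- array(0, dim = c(3, 3, n))
  R[, , 1] <- R0
  for (i in seq_len(n - 1)) {
    w <- (om[i, ] + om[i + 1, ]) / 2
    ang <- sqrt(sum(w^2)) * dt
    if (ang < 1e-14) {
      R[, , i + 1] <- R[, , i]
    } else {
      # global-frame omega: left-multiply the increment
      R[, , i + 1] <- axis_angle_matrix(w, ang) %*% R[, , i]
    }
  }
  orientation_trace(av$t, matrix_to_quat(R))
}
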