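#' Orientation and angular-velocity traces
#'
#' An orientation trace is a tibble with columns `t` (seconds, uniformly
#' sampled) and `qw, qx, qy, qz` (unit quaternion, scalar first), carrying the
#' class `orientation_trace`. An angular-velocity trace is a tibble with
#' columns `t` and `wx, wy, wz` (rad/s) plus a `frame` attribute
#' (`"global"` or `"body"`), class `angvel_trace`. Both are ordinary tibbles
#' and work with dplyr verbs; the constructors validate the invariants that
#' the kinematics layer relies on (uniform sampling, orthonormal rotations,
#' at least 3 samples for anything that will be differentiated).
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing and
#'   uniformly spaced (jitter below 1% of the nominal period).
#' @param quat n x 4 numeric matrix of quaternions (w, x, y, z); normalized on
#'   construction. Norms must be mutually consistent: rows whose norm
#'   deviates from the trace's median norm by more than `norm_tol`
#'   (relative) are rejected as drift. A uniformly scaled trace (all norms
#'   equal but away from 1) is accepted and normalized with a warning, since
#'   a constant scale carries no orientation error.
#' @param norm_tol maximum tolerated relative deviation of a row's norm from
#'   the trace median before normalization (default 1e-3).
#' @return `orientation_trace()` returns a tibble of class
#'   `orientation_trace`; `angvel_trace()` a tibble of class `angvel_trace`.
#' @examples
#' tr <- orientation_trace(seq(0, 1, by = 0.01),
#'                         matrix(rep(c(1, 0, 0, 0), 101), ncol = 4, byrow = TRUE))
#' poisson_angular_velocity(tr)
#' @export
orientation_trace <- function(t, quat, norm_tol = 1e-3) {
  t <- as.numeric(t)
  quat <- as.matrix(quat)
  if (nrow(quat) != length(t)) {
    stop_tremorkin("timestamps and quaternion rows differ in length")
  }
  check_uniform_time(t)
  nrm <- sqrt(rowSums(quat^2))
  med <- stats::median(nrm)
  if (med < 1e-12) stop_tremorkin("quaternion rows are (near) zero")
  if (any(abs(nrm / med - 1) > norm_tol)) {
    bad <- which(abs(nrm / med - 1) > norm_tol)[1]
    stop_tremorkin(sprintf(
      "quaternion norm drifts by %.2e at sample %d (tolerance %g)",
      abs(nrm[bad] / med - 1), bad, norm_tol))
  }
  if (is.finite(norm_tol) && abs(med - 1) > norm_tol) {
    rlang::warn(sprintf(
      "quaternions uniformly scaled (norm %.4g); normalized to unit norm", med))
  }
  quat <- quat / nrm
  out <- tibble::tibble(t = t, qw = quat[, 1], qx = quat[, 2],
                        qy = quat[, 3], qz = quat[, 4])
  class(out) <- c("orientation_trace", class(out))
  out
}

#' @rdname orientation_trace
#' @param omega n x 3 numeric matrix of angular velocities (rad/s).
#' @param frame `"global"` (spatial) or `"body"` frame tag.
#' @export
angvel_trace <- function(t, omega, frame = c("global", "body")) {
  frame <- match.arg(frame)
  t <- as.numeric(t)
  omega <- as.matrix(omega)
  if (nrow(omega) != length(t)) {
    stop_tremorkin("timestamps and angular-velocity rows differ in length")
  }
  check_uniform_time(t)
  out <- tibble::tibble(t = t, wx = omega[, 1], wy = omega[, 2],
                        wz = omega[, 3])
  attr(out, "frame") <- frame
  class(out) <- c("angvel_trace", class(out))
  out
}

#' @rdname orientation_trace
#' @param x an `orientation_trace`.
#' @export
as_rotation_array <- function(x) {
  quat_to_matrix(as.matrix(x[, c("qw", "qx", "qy", "qz")]))
}

trace_dt <- function(x) {
  t <- x$t
  if (length(t) < 2) stop_tremorkin("trace has fewer than 2 samples")
  mean(diff(t))
}

trace_rate <- function(x) 1 / trace_dt(x)

check_uniform_time <- function(t, jitter_frac = 0.01) {
  if (length(t) < 2) return(invisible(t))
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_tremorkin("timestamps must be strictly increasing")
  }
  period <- mean(dt)
  if (max(abs(dt - period)) > jitter_frac * period) {
    stop_tremorkin(sprintf(
      "timestamps are not uniform: jitter %.3g s exceeds %g%% of the %.3g s period",
      max(abs(dt - period)), 100 * jitter_frac, period))
  }
  invisible(t)
}

omega_matrix <- function(av) as.matrix(av[, c("wx", "wy", "wz")])

new_angvel_like <- function(template, omega, frame = attr(template, "frame")) {
  angvel_trace(template$t, omega, frame = frame %||% "global")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
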