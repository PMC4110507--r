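#' g-h filter decomposition of a movement signal
#'
#' Separates a joint angular-velocity signal into a voluntary estimate and a
#' tremor estimate with a two-state (position/velocity) g-h tracking filter
#' from the critically damped single-parameter family: the gains derive from
#' one smoothing parameter theta as \eqn{g = 1 - \theta^2},
#' \eqn{h = (1 - \theta)^2}. Voluntary movement during activities of daily
#' living lies below about 2 Hz while pathological tremor occupies 3-12 Hz,
#' so a heavy smoother (theta near 1) tracks the voluntary component and its
#' innovation residual carries the tremor. The voluntary output is the
#' one-step prediction \eqn{x_{k+1,k}}; the tremor estimate is
#' `y - voluntary`, so the decomposition is exactly additive per sample.
#'
#' @param y numeric signal (or a tibble with columns `t` plus signals; see
#'   [estimate_tremor_from_orientation()] for the full pipeline).
#' @param theta smoothing parameter in \[0, 1\]. Published tuned values are
#'   0.9952 for gyroscope input and 0.9958 for orientation-derived input.
#' @param dt sample interval in seconds.
#' @param output one of `"prediction"` (default; the one-step prediction is
#'   the voluntary estimate) or `"update"` (the filtered update).
#' @return a tibble of class `tremor_decomposition` with columns `t`, `raw`,
#'   `voluntary`, `tremor`.
#' @examples
#' t <- seq(0, 2, by = 0.001)
#' y <- sin(2 * pi * 0.5 * t) + 0.2 * sin(2 * pi * 5 * t)
#' dec <- gh_filter(y, theta = 0.9952, dt = 0.001)
#' glance(dec)
#' @export
gh_filter <- function(y, theta, dt, output = c("prediction", "update")) {
  output <- match.arg(output)
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    stop_tremorkin("theta must be a single value in [0, 1]")
  }
  if (dt <= 0) stop_tremorkin("dt must be positive")
  y <- as.numeric(y)
  gains <- gh_gains(theta)
  voluntary <- .gh_filter_core(y, gains[["g"]], gains[["h"]], dt,
                               output == "prediction")
  new_decomposition(seq_along(y) * dt - dt, y, voluntary,
                    method = "gh", theta = theta)
}

#' @rdname gh_filter
#' @return `gh_gains()` returns the named gain pair `c(g = , h = )` for a
#'   given theta.
#' @export
gh_gains <- function(theta) {
  c(g = 1 - theta^2, h = (1 - theta)^2)
}

new_decomposition <- function(t, raw, voluntary, method, theta = NA_real_) {
  out <- tibble::tibble(t = t, raw = raw, voluntary = voluntary,
                        tremor = raw - voluntary)
  attr(out, "method") <- method
  attr(out, "theta") <- theta
  class(out) <- c("tremor_decomposition", class(out))
  out
}

#' Offline low-pass reference decomposition
#'
#' The offline gold-standard tremor estimate: the voluntary component is the
#' input passed through a zero-phase (forward-backward) second-order
#' Butterworth low-pass at `fc` (default 2 Hz, the upper edge of the
#' voluntary band), and the tremor estimate is the residual. Zero-phase
#' filtering is acausal, which is why this reference cannot run in real time
#' but serves to benchmark the online g-h estimate.
#'
#' @param y numeric signal.
#' @param rate sampling rate of `y` in Hz.
#' @param fc low-pass cutoff in Hz; must be below the Nyquist rate.
#' @return a `tremor_decomposition` tibble (see [gh_filter()]).
#' @export
offline_reference <- function(y, rate, fc = 2) {
  if (fc >= rate / 2) {
    stop_tremorkin(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)",
                           fc, rate / 2))
  }
  y <- as.numeric(y)
  bf <- signal::butter(2, fc / (rate / 2), type = "low")
  # reflect the signal about its endpoints before the forward-backward pass:
  # the recursive filter starts from zero state, so an unpadded run would
  # smear an edge transient of ~1/fc into the estimate (worst on signals
  # with a non-zero start, e.g. a DC offset)
  n <- length(y)
  n_pad <- min(n - 1, ceiling(3 * rate / fc))
  mu <- mean(y)
  yc <- y - mu
  padded <- c(2 * yc[1] - yc[(n_pad + 1):2],
              yc,
              2 * yc[n] - yc[(n - 1):(n - n_pad)])
  filtered <- as.numeric(signal::filtfilt(bf, padded))
  voluntary <- filtered[(n_pad + 1):(n_pad + n)] + mu
  new_decomposition(seq_along(y) / rate - 1 / rate, as.numeric(y), voluntary,
                    method = "offline")
}

#' Tremor decomposition of a joint from a trial's orientation data
#'
#' Full orientation pipeline for one joint: Poisson-equation angular velocity
#' per sensor, proximal-distal subtraction, linear upsampling to
#' `upsample_rate` (1 kHz by default, so the tracking filter runs at the
#' rate a neuroprosthesis controller would), then per-axis g-h decomposition.
#' A norm channel (Euclidean norm of the three raw/voluntary/tremor vectors)
#' is derived after filtering.
#'
#' @param trial a [trial_recording()].
#' @param joint either the name of a joint (`"wrist"`: the two most distal
#'   sensors in `reference_order`) or a length-2 character vector
#'   `c(distal_id, proximal_id)`.
#' @param theta g-h smoothing parameter (default 0.9958, the tuned value for
#'   orientation-derived input).
#' @param upsample_rate target rate in Hz before filtering (default 1000).
#' @param reference `"offline"` to also compute the offline reference
#'   decomposition per axis, `"none"` to skip it.
#' @return a list of class `joint_decomposition` with elements `axes` (named
#'   list x/y/z/norm of `tremor_decomposition` tibbles), `reference` (same
#'   shape or NULL), `joint`, `theta`, `rate`.
#' @export
estimate_tremor_from_orientation <- function(trial, joint = "wrist",
                                             theta = 0.9958,
                                             upsample_rate = 1000,
                                             reference = c("none", "offline")) {
  reference <- match.arg(reference)
  pair <- resolve_joint(trial, joint)
  y <- joint_velocity_series(trial, pair, upsample_rate)
  decompose_joint_velocity(y, theta, upsample_rate, reference,
                           joint = paste(pair, collapse = "-"))
}

resolve_joint <- function(trial, joint) {
  if (length(joint) == 1 && joint %in% c("wrist", "elbow")) {
    idx <- if (joint == "wrist") 1:2 else c(2, length(trial$reference_order))
    pair <- trial$reference_order[idx]
  } else if (length(joint) == 2) {
    pair <- as.character(joint)
  } else {
    stop_tremorkin("joint must be a joint name or a c(distal, proximal) pair")
  }
  missing <- setdiff(pair, names(trial$sensors))
  if (length(missing) > 0) {
    stop_tremorkin(paste0("sensor(s) not in trial: ",
                          paste(missing, collapse = ", ")))
  }
  pair
}

joint_velocity_series <- function(trial, pair, upsample_rate) {
  distal <- poisson_angular_velocity(trial$sensors[[pair[1]]])
  proximal <- poisson_angular_velocity(trial$sensors[[pair[2]]])
  jv <- joint_angular_velocity(distal, proximal)
  resample_series(jv, upsample_rate)
}

decompose_joint_velocity <- function(y, theta, rate, reference, joint) {
  axes <- c("wx", "wy", "wz")
  dec <- lapply(axes, function(a) gh_filter(y[[a]], theta, 1 / rate))
  names(dec) <- c("x", "y", "z")
  for (a in names(dec)) dec[[a]]$t <- y$t
  dec$norm <- norm_channel(dec)
  ref <- NULL
  if (reference == "offline") {
    ref <- lapply(axes, function(a) {
      r <- offline_reference(y[[a]], rate)
      r$t <- y$t
      r
    })
    names(ref) <- c("x", "y", "z")
    ref$norm <- norm_channel(ref)
  }
  structure(list(axes = dec, reference = ref, joint = joint,
                 theta = theta, rate = rate),
            class = "joint_decomposition")
}

norm_channel <- function(dec) {
  n <- new_decomposition(
    dec$x$t,
    sqrt(dec$x$raw^2 + dec$y$raw^2 + dec$z$raw^2),
    sqrt(dec$x$voluntary^2 + dec$y$voluntary^2 + dec$z$voluntary^2),
    method = attr(dec$x, "method"), theta = attr(dec$x, "theta"))
  n
}

#' @export
print.joint_decomposition <- function(x, ...) {
  cat(sprintf("<joint_decomposition joint %s, theta = %.4f, %g Hz, %d samples>\n",
              x$joint, x$theta, x$rate, nrow(x$axes$x)))
  invisible(x)
}
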