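#' Kinematic tracking error (KTE)
#'
#' Scores a tremor estimate against a reference as
#' \eqn{KTE = \varphi^2_{|b|} + \sigma^2_{|b|}} where
#' \eqn{b_k = |estimate_k - reference_k|}: the first component is the mean of
#' the absolute estimation error and gauges how quickly the tracker reacts to
#' velocity changes; the second is the (population) variance of the absolute
#' error and gauges smoothness. KTE is non-negative, zero iff the series are
#' identical, and invariant to adding the same constant to both series.
#'
#' @param estimate,reference numeric series of equal length (>= 2).
#' @return a one-row tibble of class `kte_result` with columns `kte`, `kte1`
#'   (mean |b|), `kte2` (population variance of |b|), `n_samples`.
#' @examples
#' kte(c(1, 2, 3), c(1, 1, 1))  # kte1 = 1, kte2 = 2/3
#' @export
kte <- function(estimate, reference) {
  if (length(estimate) != length(reference)) {
    stop_tremorkin("estimate and reference must have equal length")
  }
  if (length(estimate) < 2) {
    stop_tremorkin("KTE needs at least 2 samples")
  }
  b <- abs(estimate - reference)
  kte1 <- mean(b)
  kte2 <- pop_var(b)
  out <- tibble::tibble(kte = kte1 + kte2, kte1 = kte1, kte2 = kte2,
                        n_samples = length(b))
  class(out) <- c("kte_result", class(out))
  out
}

#' Compare tremor-estimation pipelines on one trial
#'
#' Runs the orientation-based pipeline (Poisson angular velocity from the
#' stored orientation stream) and, when the trial carries a ground-truth
#' gyroscope channel (synthetic trials do), the gyroscope-based pipeline on
#' the same joint, and scores each g-h tremor estimate against the offline
#' low-pass reference computed from the gyroscope channel. The per-axis and
#' norm-channel KTE components are reported separately, which is how the lag
#' introduced by an onboard orientation fusion filter shows up: it inflates
#' the first (response-time) component of the orientation method.
#'
#' @param trial a [trial_recording()]; for the gyroscope arm it must carry
#'   `ground_truth$gyro` (a named list of [angvel_trace()] per sensor).
#' @param theta g-h smoothing parameter used for both pipelines.
#' @param joint joint spec as in [estimate_tremor_from_orientation()].
#' @param upsample_rate filter rate in Hz (default 1000).
#' @return a tibble with columns `method` (`"orientation"`, `"gyroscope"`),
#'   `channel` (`x`, `y`, `z`, `norm`), `kte`, `kte1`, `kte2`.
#' @export
compare_methods <- function(trial, theta, joint = "wrist",
                            upsample_rate = 1000) {
  pair <- resolve_joint(trial, joint)
  gt <- trial$ground_truth
  if (is.null(gt$gyro)) {
    stop_tremorkin("trial has no ground-truth gyroscope channel; cannot compare methods")
  }
  gy <- resample_series(
    joint_angular_velocity(gt$gyro[[pair[1]]], gt$gyro[[pair[2]]]),
    upsample_rate)
  ref <- decompose_joint_velocity(gy, theta, upsample_rate, "offline",
                                  joint = paste(pair, collapse = "-"))$reference
  orient <- estimate_tremor_from_orientation(trial, joint = pair,
                                             theta = theta,
                                             upsample_rate = upsample_rate)
  gyro <- decompose_joint_velocity(gy, theta, upsample_rate, "none",
                                   joint = paste(pair, collapse = "-"))$axes
  score <- function(axes, method) {
    purrr::imap_dfr(axes, function(dec, ch) {
      dplyr::bind_cols(tibble::tibble(method = method, channel = ch),
                       kte(dec$tremor, ref[[ch]]$tremor)[, 1:3])
    })
  }
  dplyr::bind_rows(score(orient$axes, "orientation"),
                   score(gyro, "gyroscope"))
}

#' Single-sided amplitude spectrum
#'
#' Amplitude spectrum of a detrended (mean-removed) uniformly sampled
#' series: a pure sinusoid of amplitude A yields a peak of height A at its
#' frequency (up to spectral leakage when the record does not hold a whole
#' number of cycles).
#'
#' @param x numeric series, uniform sampling.
#' @param rate sampling rate in Hz.
#' @return a tibble with columns `frequency` (Hz, from 0 to Nyquist) and
#'   `amplitude`.
#' @export
amplitude_spectrum <- function(x, rate) {
  x <- as.numeric(x)
  x <- x - mean(x)
  n <- length(x)
  sp <- fft(x)
  half <- seq_len(floor(n / 2) + 1)
  amp <- Mod(sp[half]) / n
  # fold the two-sided spectrum: every non-DC, non-Nyquist bin appears twice
  interior <- 2:(length(half) - if (n %% 2 == 0) 1 else 0)
  amp[interior] <- 2 * amp[interior]
  out <- tibble::tibble(frequency = (half - 1) * rate / n, amplitude = amp)
  class(out) <- c("amplitude_spectrum", class(out))
  out
}

#' @rdname amplitude_spectrum
#' @param spectrum a tibble from `amplitude_spectrum()`.
#' @param band optional frequency band `c(lo, hi)` to search within.
#' @return `spectral_peak()` returns a one-row tibble `frequency`,
#'   `amplitude` at the largest amplitude bin.
#' @export
spectral_peak <- function(spectrum, band = NULL) {
  sp <- spectrum
  if (!is.null(band)) {
    sp <- dplyr::filter(sp, .data$frequency >= band[1],
                        .data$frequency <= band[2])
  }
  sp[which.max(sp$amplitude), c("frequency", "amplitude")]
}
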