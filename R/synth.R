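#' Configuration for the synthetic finger-to-nose generator
#'
#' Collects the parameters of the simulated recording session. Defaults
#' emulate the clinical finger-to-nose protocol the algorithms target: 30 s
#' trials holding 3 nose-knee cycles (cycle fundamental 0.1 Hz), sensors
#' sampled at 100 Hz, kinetic tremor at 5 Hz within the pathological 3-12 Hz
#' band, and motion amplitude growing toward the hand because each joint adds
#' its own rotation on top of the proximal segments' motion.
#'
#' @param configuration sensor layout, one of [trial_configurations()].
#' @param duration trial length in seconds (default 30).
#' @param n_cycles finger-to-nose cycles per trial (default 3).
#' @param sample_rate sensor sampling rate in Hz (default 100).
#' @param voluntary_amp peak humerus angular velocity in rad/s (default 0.6).
#' @param distal_gain per-segment ratio of voluntary motion magnitude,
#'   distal over proximal (> 1; default 1.8).
#' @param tremor_freq tremor frequency in Hz, within \[3, 12\] (default 5).
#' @param tremor_amp_distal peak tremor angular velocity at the hand in
#'   rad/s (default 1.5).
#' @param tremor_gain per-segment attenuation of tremor toward the shoulder
#'   (> 1; default 2.5).
#' @param forearm_gradient fraction of forearm pronosupination reaching a
#'   proximally placed forearm sensor (default 0.6; the forearm is not rigid
#'   for rotation about its long axis, which is what makes two forearm
#'   sensors distinguishable at all).
#' @param noise_sd white-noise standard deviation on angular velocity in
#'   rad/s (default 0.02).
#' @param ekf_lag_cutoff cutoff (Hz) of a first-order low-pass applied to
#'   the stored orientation stream, emulating the response-time limit of an
#'   onboard orientation fusion filter; `NULL` (default) disables it.
#' @param seed integer seed for the trial's random draws (phases, noise).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(configuration = "three_mimu_distal",
                         duration = 30, n_cycles = 3, sample_rate = 100,
                         voluntary_amp = 0.6, distal_gain = 1.8,
                         tremor_freq = 5, tremor_amp_distal = 1.5,
                         tremor_gain = 2.5, forearm_gradient = 0.6,
                         noise_sd = 0.02, ekf_lag_cutoff = NULL,
                         seed = 1L) {
  configuration <- match.arg(configuration, trial_configurations())
  if (tremor_freq < 3 || tremor_freq > 12) {
    stop_tremorkin("tremor_freq must lie in the pathological band [3, 12] Hz")
  }
  f0 <- n_cycles / duration
  if (f0 >= 2) {
    stop_tremorkin("cycle fundamental must stay below the 2 Hz voluntary band edge")
  }
  if (distal_gain <= 1 || tremor_gain <= 1) {
    stop_tremorkin("distal_gain and tremor_gain must exceed 1")
  }
  structure(list(configuration = configuration, duration = duration,
                 n_cycles = n_cycles, sample_rate = sample_rate,
                 voluntary_amp = voluntary_amp, distal_gain = distal_gain,
                 tremor_freq = tremor_freq,
                 tremor_amp_distal = tremor_amp_distal,
                 tremor_gain = tremor_gain,
                 forearm_gradient = forearm_gradient,
                 noise_sd = noise_sd, ekf_lag_cutoff = ekf_lag_cutoff,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_sensor_ids <- function(configuration) {
  switch(configuration,
         four_mimu = c("hand", "distal_forearm", "proximal_forearm", "humerus"),
         three_mimu_distal = c("hand", "distal_forearm", "humerus"),
         three_mimu_proximal = c("hand", "proximal_forearm", "humerus"))
}

#' Simulate one finger-to-nose trial with ground truth
#'
#' Builds an additive kinematic chain: the humerus rotates with a smooth
#' periodic elevation profile at the cycle fundamental; each more distal
#' segment adds its own joint rotation (forearm pronosupination about the
#' segment's long axis, wrist flexion) so angular-velocity magnitude grows
#' strictly toward the hand. In the four-sensor layout the proximally placed
#' forearm sensor receives only `forearm_gradient` of the pronosupination
#' (soft-tissue / non-rigid forearm). Tremor is an amplitude-modulated
#' sinusoid at `tremor_freq` (slow raised-cosine envelope, task-dependent
#' kinetic tremor), largest at the hand and attenuated by `tremor_gain` per
#' proximal segment; white noise is folded into the tremor component so that
#' total = voluntary + tremor holds exactly per sample. Orientations are
#' produced by exact axis-angle integration of the total angular velocity,
#' and the ground-truth gyroscope channel is the Poisson-extracted angular
#' velocity of that (lag-free) orientation stream — what an ideal
#' strapped-down gyro would report in this simulated world. When
#' `ekf_lag_cutoff` is set, the stored orientation stream is additionally
#' low-passed to emulate the lag of an onboard fusion filter; the gyroscope
#' channel stays lag-free.
#'
#' @param config a [synth_config()].
#' @return a [trial_recording()] whose `ground_truth` element holds, per
#'   sensor: `voluntary`, `tremor`, `total`, `gyro` ([angvel_trace()]s) and
#'   `orientation` (the lag-free [orientation_trace()]); plus `config`.
#' @examples
#' trial <- simulate_trial(synth_config(seed = 42))
#' compute_features(trial)
#' @export
simulate_trial <- function(config = synth_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = 1 / config$sample_rate)
  n <- length(t)
  f0 <- config$n_cycles / config$duration

  # per-joint voluntary angular-velocity profiles (orthogonal dominant axes)
  profile <- function() periodic_profile(t, f0, n_harmonics = 5)
  joint_axes <- list(shoulder = c(0.15, 0.97, 0.20),
                     pronosupination = c(0.97, 0.10, 0.22),
                     wrist = c(0.20, 0.15, 0.97))
  joint_axes <- lapply(joint_axes, function(a) a / sqrt(sum(a^2)))
  # own-joint amplitudes sized so segment magnitude grows by distal_gain
  # per level: RMS^2 adds along the chain for near-orthogonal axes
  g2 <- config$distal_gain^2
  amps <- config$voluntary_amp *
    c(shoulder = 1, pronosupination = sqrt(g2 - 1),
      wrist = sqrt(g2^2 - g2))
  w_joint <- list(
    shoulder = outer(amps[["shoulder"]] * profile(), joint_axes$shoulder),
    pronosupination = outer(amps[["pronosupination"]] * profile(),
                            joint_axes$pronosupination),
    wrist = outer(amps[["wrist"]] * profile(), joint_axes$wrist))

  ids <- synth_sensor_ids(config$configuration)
  # chain position within this trial, 1 = hand; tremor attenuates with
  # distance from the hand along the instrumented chain
  level <- stats::setNames(seq_along(ids), ids)

  voluntary <- lapply(ids, function(id) {
    w <- w_joint$shoulder
    if (id %in% c("distal_forearm", "hand")) {
      w <- w + w_joint$pronosupination
    } else if (id == "proximal_forearm") {
      w <- w + config$forearm_gradient * w_joint$pronosupination
    }
    if (id == "hand") w <- w + w_joint$wrist
    w
  })
  names(voluntary) <- ids

  # kinetic tremor: common waveform along the chain, attenuated proximally
  env <- 0.3 + 0.7 * (0.5 - 0.5 * cos(2 * pi * f0 * t))
  phase <- stats::runif(1, 0, 2 * pi)
  trem_axis <- c(0.25, 0.20, 0.95); trem_axis <- trem_axis / sqrt(sum(trem_axis^2))
  trem_wave <- env * sin(2 * pi * config$tremor_freq * t + phase)
  tremor <- lapply(ids, function(id) {
    amp <- config$tremor_amp_distal / config$tremor_gain^(level[[id]] - 1)
    outer(amp * trem_wave, trem_axis) +
      matrix(stats::rnorm(3 * n, sd = config$noise_sd), n, 3)
  })
  names(tremor) <- ids

  truth <- list(config = config, sensors = list())
  sensors <- list()
  for (id in ids) {
    total <- voluntary[[id]] + tremor[[id]]
    av_total <- angvel_trace(t, total)
    orient_clean <- integrate_orientation(av_total)
    gyro <- poisson_angular_velocity(orient_clean)
    stored <- orient_clean
    if (!is.null(config$ekf_lag_cutoff)) {
      stored <- lowpass_orientation(orient_clean, config$ekf_lag_cutoff)
    }
    sensors[[id]] <- stored
    truth$sensors[[id]] <- list(
      voluntary = angvel_trace(t, voluntary[[id]]),
      tremor = angvel_trace(t, tremor[[id]]),
      total = av_total,
      gyro = gyro,
      orientation = orient_clean,
      location = level[[id]])
  }
  truth$gyro <- lapply(truth$sensors, `[[`, "gyro")

  trial_recording(
    trial_id = sprintf("synth-%s-seed%d", config$configuration, config$seed),
    configuration = config$configuration,
    sensors = sensors,
    reference_order = ids,
    sample_rate = config$sample_rate,
    ground_truth = truth)
}

# smooth periodic unit-peak profile: harmonics of the cycle fundamental with
# 1/k^2 amplitude decay and random phases (stays inside the < 2 Hz band)
periodic_profile <- function(t, f0, n_harmonics = 5) {
  ph <- stats::runif(n_harmonics, 0, 2 * pi)
  w <- rowSums(sapply(seq_len(n_harmonics), function(k) {
    sin(2 * pi * k * f0 * t + ph[k]) / k^2
  }))
  w / max(abs(w))
}

# first-order low-pass on quaternion components, renormalized: emulates the
# bandwidth limit of onboard orientation fusion
lowpass_orientation <- function(trace, fc) {
  q <- as.matrix(trace[, c("qw", "qx", "qy", "qz")])
  dt <- trace_dt(trace)
  alpha <- dt / (dt + 1 / (2 * pi * fc))
  out <- q
  for (i in 2:nrow(q)) {
    out[i, ] <- out[i - 1, ] + alpha * (q[i, ] - out[i - 1, ])
  }
  orientation_trace(trace$t, quat_normalize(out), norm_tol = Inf)
}

#' Generate a reproducible suite of synthetic trials
#'
#' Draws `n_trials` trials from a template configuration with per-trial
#' variation mimicking a patient cohort: voluntary amplitude jittered by
#' +/- 30%, and tremor severity swept log-uniformly over a 50-fold range so
#' the suite spans near-absent to severe kinetic tremor. The same seed
#' always yields the identical suite.
#'
#' @param n_trials number of trials (>= 1).
#' @param template a [synth_config()] used as the base for every trial.
#' @param seed master seed; per-trial seeds are derived from it.
#' @param configurations `"fixed"` keeps the template's sensor layout for
#'   every trial, `"cycle"` rotates through all three layouts.
#' @param severity_range range of multiplicative tremor-severity scales
#'   applied to `tremor_amp_distal` (default 0.05 to 2.5).
#' @return a list of [trial_recording()]s.
#' @export
make_fixture_suite <- function(n_trials, template = synth_config(),
                               seed = 1L,
                               configurations = c("fixed", "cycle"),
                               severity_range = c(0.05, 2.5)) {
  configurations <- match.arg(configurations)
  if (n_trials < 1) stop_tremorkin("n_trials must be at least 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  jitter <- stats::runif(n_trials, 0.7, 1.3)
  severity <- exp(seq(log(severity_range[1]), log(severity_range[2]),
                      length.out = n_trials))
  severity <- sample(severity)  # decouple severity from trial index
  configs <- trial_configurations()
  lapply(seq_len(n_trials), function(i) {
    cfg <- template
    cfg$seed <- sub_seeds[i]
    cfg$voluntary_amp <- template$voluntary_amp * jitter[i]
    cfg$tremor_amp_distal <- template$tremor_amp_distal * severity[i]
    if (configurations == "cycle") {
      cfg$configuration <- configs[(i - 1L) %% 3L + 1L]
    }
    trial <- simulate_trial(cfg)
    trial$trial_id <- sprintf("%s-%02d", trial$trial_id, i)
    trial
  })
}
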