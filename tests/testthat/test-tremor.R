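test_that("gains derive from theta by the critically damped rule", {
  g <- gh_gains(0.9952)
  expect_equal(unname(g["g"]), 1 - 0.9952^2)
  expect_equal(unname(g["h"]), (1 - 0.9952)^2)
  expect_error(gh_filter(1:10, theta = 1.5, dt = 0.01), "theta")
})

test_that("constant input passes entirely into the voluntary channel", {
  for (theta in c(0, 0.5, 0.9952, 1)) {
    dec <- gh_filter(rep(2.5, 500), theta, dt = 0.001)
    expect_equal(dec$voluntary, rep(2.5, 500))
    expect_equal(dec$tremor, rep(0, 500))
  }
})

test_that("theta = 0 tracks a linear ramp with vanishing steady-state error", {
  t <- seq(0, 1, by = 0.001)
  dec <- gh_filter(3 * t, theta = 0, dt = 0.001)
  tail_err <- abs(dec$tremor[t > 0.5])
  expect_lt(max(tail_err), 1e-10)
})

test_that("decomposition is exactly additive and linear", {
  set.seed(3)
  y1 <- cumsum(rnorm(2000)) / 10
  y2 <- sin(2 * pi * 5 * seq_len(2000) / 1000)
  d1 <- gh_filter(y1, 0.99, 0.001)
  d2 <- gh_filter(y2, 0.99, 0.001)
  d12 <- gh_filter(y1 + y2, 0.99, 0.001)
  expect_equal(d12$raw, d12$voluntary + d12$tremor, tolerance = 1e-14)
  expect_equal(d12$voluntary, d1$voluntary + d2$voluntary, tolerance = 1e-12)
  expect_equal(d12$tremor, d1$tremor + d2$tremor, tolerance = 1e-12)
})

test_that("steady-state tremor gain at 5 Hz matches the closed-form response", {
  rate <- 1000; f <- 5; theta <- 0.9952
  t <- seq(0, 10, by = 1 / rate)
  dec <- gh_filter(sin(2 * pi * f * t), theta, 1 / rate)
  measured <- sine_amplitude(dec$tremor, t, f, keep = t > 5)
  expect_equal(measured, gh_error_response(theta, f, rate), tolerance = 0.01)
})

test_that("tremor-band leakage grows monotonically with theta", {
  rate <- 1000; f <- 5
  t <- seq(0, 4, by = 1 / rate)
  amps <- vapply(c(0.3, 0.6, 0.9, 0.99), function(theta) {
    dec <- gh_filter(sin(2 * pi * f * t), theta, 1 / rate)
    sine_amplitude(dec$tremor, t, f, keep = t > 2)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("theta limits behave as pure extrapolation vs exact tracking", {
  t <- seq(0, 2, by = 0.001)
  y <- 1 + sin(2 * pi * 1 * t)
  # theta = 1: gains are zero, prediction never leaves the initial state
  d1 <- gh_filter(y, 1, 0.001)
  expect_equal(d1$voluntary, rep(y[1], length(y)))
  # theta = 0: residual dies out (exact constant-velocity tracker)
  d0 <- gh_filter(y, 0, 0.001)
  expect_lt(mean(abs(d0$tremor[t > 1])), 1e-4)
})

test_that("offline reference separates pass band from stop band", {
  rate <- 100
  t <- seq(0, 20, by = 1 / rate)
  dc <- offline_reference(rep(1.3, length(t)), rate)
  expect_lt(max(abs(dc$tremor)), 1e-9)

  slow <- sin(2 * pi * 0.2 * t)
  ds <- offline_reference(slow, rate)
  expect_lt(rms(ds$tremor), 0.05 * rms(slow))

  fast <- sin(2 * pi * 8 * t)
  df <- offline_reference(fast, rate)
  expect_gt(rms(df$tremor), 0.95 * rms(fast))

  expect_error(offline_reference(fast, rate, fc = 60), "Nyquist")
})

test_that("full orientation pipeline decomposes a synthetic trial per axis", {
  trial <- simulate_trial(quick_config(seed = 17))
  dec <- estimate_tremor_from_orientation(trial, theta = 0.9958,
                                          reference = "offline")
  for (ch in c("x", "y", "z", "norm")) {
    d <- dec$axes[[ch]]
    expect_equal(d$raw, d$voluntary + d$tremor, tolerance = 1e-14)
  }
  expect_equal(nrow(dec$axes$x), 10 * 1000 + 1)  # upsampled to 1 kHz
  expect_false(is.null(dec$reference))
  # tremor channel peaks at the configured tremor frequency
  sp <- amplitude_spectrum(dec$axes$z$tremor, 1000)
  pk <- spectral_peak(sp, band = c(3, 12))
  expect_lt(abs(pk$frequency - 5), 0.2)
})

test_that("swapping distal and proximal sensors negates all channels", {
  trial <- simulate_trial(quick_config(seed = 23))
  pair <- trial$reference_order[1:2]
  a <- estimate_tremor_from_orientation(trial, joint = pair, theta = 0.995)
  b <- estimate_tremor_from_orientation(trial, joint = rev(pair), theta = 0.995)
  for (ch in c("x", "y", "z")) {
    expect_equal(b$axes[[ch]]$raw, -a$axes[[ch]]$raw, tolerance = 1e-12)
    expect_equal(b$axes[[ch]]$voluntary, -a$axes[[ch]]$voluntary,
                 tolerance = 1e-12)
    expect_equal(b$axes[[ch]]$tremor, -a$axes[[ch]]$tremor, tolerance = 1e-12)
  }
  expect_error(estimate_tremor_from_orientation(trial, joint = c("hand", "nope")),
               "not in trial")
})

test_that("zero-tremor leakage matches the transfer-function prediction", {
  trial <- simulate_trial(synth_config(seed = 2, tremor_amp_distal = 0,
                                       noise_sd = 0))
  dec <- estimate_tremor_from_orientation(trial, theta = 0.9958)
  d <- dec$axes$z
  # frequency-domain prediction: scale each Fourier component of the raw
  # signal by the closed-form error response and compare total leaked power
  n <- length(d$raw)
  x <- d$raw - mean(d$raw)
  amp <- Mod(fft(x)) / n
  freqs <- (seq_len(n) - 1) * 1000 / n
  H <- gh_error_response(0.9958, pmin(freqs, 1000 - freqs), 1000)
  predicted_rms <- sqrt(sum((amp * H)^2))
  measured_rms <- rms(d$tremor - mean(d$tremor))
  expect_equal(measured_rms, predicted_rms, tolerance = 0.05)
  # and the leak stays a small fraction of the voluntary motion
  expect_lt(rms(d$tremor), 0.06 * rms(d$voluntary))
})
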