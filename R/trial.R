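#' Trial recordings
#'
#' A trial recording bundles one finger-to-nose trial: an orientation trace
#' per sensor, the sensor configuration, and the distal-to-proximal reference
#' order of the chain (position 1 = hand). The three supported configurations
#' mirror a four-sensor neuroprosthesis layout (hand, distal forearm,
#' proximal forearm, humerus) and the two three-sensor biomechanics layouts
#' that keep one forearm sensor, either distal or proximal.
#'
#' @param trial_id character scalar identifying the trial.
#' @param configuration one of `"four_mimu"`, `"three_mimu_distal"`,
#'   `"three_mimu_proximal"`. Four-sensor configurations must carry 4 sensors,
#'   three-sensor ones 3.
#' @param sensors named list of [orientation_trace()] objects; names are the
#'   sensor ids. All traces must share timestamps.
#' @param reference_order character vector of sensor ids ordered from most
#'   distal (hand) to most proximal (humerus); must be a permutation of
#'   `names(sensors)`.
#' @param sample_rate nominal sampling rate in Hz.
#' @param true_locations optional named integer vector mapping sensor id to
#'   its true chain ordinal (1 = hand); defaults to the positions implied by
#'   `reference_order`.
#' @param ground_truth optional list attached by the synthetic generator (see
#'   [simulate_trial()]); carried along, not validated here.
#' @return a validated list of class `trial_recording`.
#' @seealso [read_trial()], [write_trial()], [simulate_trial()]
#' @export
trial_recording <- function(trial_id, configuration, sensors, reference_order,
                            sample_rate, true_locations = NULL,
                            ground_truth = NULL) {
  configuration <- match.arg(configuration, trial_configurations())
  if (length(sensors) == 0) {
    stop_tremorkin("trial has no sensors")
  }
  if (is.null(names(sensors)) || any(names(sensors) == "")) {
    stop_tremorkin("sensors must be a named list")
  }
  n_expected <- if (configuration == "four_mimu") 4L else 3L
  if (length(sensors) != n_expected) {
    stop_tremorkin(sprintf("configuration '%s' requires %d sensors, got %d",
                           configuration, n_expected, length(sensors)))
  }
  if (!setequal(reference_order, names(sensors)) ||
      length(reference_order) != length(sensors)) {
    stop_tremorkin("reference_order must be a permutation of the sensor ids")
  }
  t0 <- sensors[[1]]$t
  for (s in names(sensors)) {
    tr <- sensors[[s]]
    if (!inherits(tr, "orientation_trace")) {
      stop_tremorkin(sprintf("sensor '%s' is not an orientation_trace", s))
    }
    if (nrow(tr) != length(t0) || max(abs(tr$t - t0)) > 1e-9) {
      stop_tremorkin("all sensor traces must share length and timestamps")
    }
  }
  if (is.null(true_locations)) {
    true_locations <- stats::setNames(seq_along(reference_order),
                                      reference_order)
  }
  structure(
    list(trial_id = as.character(trial_id),
         configuration = configuration,
         sensors = sensors,
         reference_order = as.character(reference_order),
         sample_rate = as.numeric(sample_rate),
         true_locations = true_locations,
         ground_truth = ground_truth),
    class = "trial_recording")
}

trial_configurations <- function() {
  c("four_mimu", "three_mimu_distal", "three_mimu_proximal")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording '%s'>\n", x$trial_id))
  cat(sprintf("  configuration: %s (%d sensors)\n",
              x$configuration, length(x$sensors)))
  cat(sprintf("  chain (distal to proximal): %s\n",
              paste(x$reference_order, collapse = " > ")))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n",
              nrow(x$sensors[[1]]), x$sample_rate,
              diff(range(x$sensors[[1]]$t))))
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' @rdname trial_recording
#' @param x a `trial_recording`.
#' @return `trial_sensor_table()` returns all sensors' quaternion samples as
#'   one long tibble with a `sensor_id` column.
#' @export
trial_sensor_table <- function(x) {
  purrr::imap_dfr(x$sensors, function(tr, id) {
    dplyr::mutate(tibble::as_tibble(tr), sensor_id = id, .before = 1)
  })
}
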