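#' Read and write trial recordings as plain-text CSV
#'
#' The on-disk trial format is a single CSV-like text file: `#`-prefixed
#' header lines (`trial_id`, `configuration`, `reference_order`,
#' `sample_rate`, optionally `true_locations`), then one block per sensor
#' introduced by `# sensor=<id>` with a `t,qw,qx,qy,qz` column line and one
#' data row per sample. A 9-column rotation-matrix block
#' (`t,r11,r12,...,r33`, row-major) is accepted as an alternative;
#' matrices drifted off SO(3) beyond a tolerance are re-orthonormalized with
#' a warning. Quaternions are normalized on read; rows whose norm deviates
#' from 1 by more than 1e-3 are rejected. Numbers are written with 17
#' significant digits so a write-read round trip is an identity to near
#' machine precision.
#'
#' @param path file path.
#' @return `read_trial()` returns a validated [trial_recording()].
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop_tremorkin(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  sensors <- list()
  current <- NULL
  colnames_cur <- NULL
  rows <- list()
  flush_block <- function() {
    if (is.null(current)) return()
    if (length(rows) == 0) {
      stop_tremorkin(sprintf("sensor block '%s' has no data rows", current))
    }
    m <- do.call(rbind, rows)
    sensors[[current]] <<- parse_sensor_block(m, colnames_cur, current)
    rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop_tremorkin(paste0("malformed header line: ", ln),
                       class = "tremorkin_format_error")
      }
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "sensor") {
        flush_block()
        current <- val
        colnames_cur <- NULL
      } else {
        header[[key]] <- val
      }
    } else if (is.null(colnames_cur) && !is.null(current)) {
      colnames_cur <- trimws(strsplit(ln, ",")[[1]])
    } else if (!is.null(current)) {
      v <- suppressWarnings(as.numeric(strsplit(ln, ",")[[1]]))
      if (anyNA(v)) {
        stop_tremorkin(paste0("non-numeric data row: ", ln),
                       class = "tremorkin_format_error")
      }
      rows[[length(rows) + 1]] <- v
    } else {
      stop_tremorkin(paste0("data before any '# sensor=' block: ", ln),
                     class = "tremorkin_format_error")
    }
  }
  flush_block()
  required <- c("trial_id", "configuration", "reference_order", "sample_rate")
  missing <- setdiff(required, names(header))
  if (length(missing) > 0) {
    stop_tremorkin(paste0("missing header line(s): ",
                          paste(missing, collapse = ", ")),
                   class = "tremorkin_format_error")
  }
  true_locations <- NULL
  if (!is.null(header$true_locations)) {
    pairs <- strsplit(strsplit(header$true_locations, ",")[[1]], ":")
    true_locations <- stats::setNames(
      as.integer(vapply(pairs, `[`, "", 2)),
      trimws(vapply(pairs, `[`, "", 1)))
  }
  trial_recording(
    trial_id = header$trial_id,
    configuration = header$configuration,
    sensors = sensors,
    reference_order = trimws(strsplit(header$reference_order, ",")[[1]]),
    sample_rate = as.numeric(header$sample_rate),
    true_locations = true_locations)
}

parse_sensor_block <- function(m, cols, sensor_id, ortho_tol = 1e-6) {
  if (is.null(cols)) {
    stop_tremorkin(sprintf("sensor block '%s' lacks a column line", sensor_id),
                   class = "tremorkin_format_error")
  }
  if (identical(cols, c("t", "qw", "qx", "qy", "qz"))) {
    orientation_trace(m[, 1], m[, 2:5])
  } else if (length(cols) == 10 && cols[1] == "t") {
    n <- nrow(m)
    R <- array(0, dim = c(3, 3, n))
    # matrix rows are stored row-major: r11,r12,r13,r21,...
    for (i in seq_len(n)) {
      mi <- matrix(m[i, -1], 3, 3, byrow = TRUE)
      err <- max(abs(crossprod(mi) - diag(3)))
      if (err > ortho_tol) {
        rlang::warn(sprintf(
          "sensor '%s': rotation matrix off SO(3) by %.2e at sample %d; re-orthonormalized",
          sensor_id, err, i))
        mi <- reorthonormalize(mi)
      }
      R[, , i] <- mi
    }
    orientation_trace(m[, 1], matrix_to_quat(R))
  } else {
    stop_tremorkin(sprintf(
      "sensor block '%s': unsupported columns '%s'", sensor_id,
      paste(cols, collapse = ",")), class = "tremorkin_format_error")
  }
}

#' @rdname read_trial
#' @param trial a [trial_recording()].
#' @export
write_trial <- function(trial, path) {
  if (!inherits(trial, "trial_recording")) {
    stop_tremorkin("write_trial expects a trial_recording")
  }
  if (length(trial$sensors) == 0) stop_tremorkin("trial has no sensors")
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# trial_id=%s", trial$trial_id)
  wl("# configuration=%s", trial$configuration)
  wl("# reference_order=%s", paste(trial$reference_order, collapse = ","))
  wl("# sample_rate=%.17g", trial$sample_rate)
  if (!is.null(trial$true_locations)) {
    wl("# true_locations=%s",
       paste(sprintf("%s:%d", names(trial$true_locations),
                     as.integer(trial$true_locations)), collapse = ","))
  }
  for (id in names(trial$sensors)) {
    tr <- trial$sensors[[id]]
    wl("# sensor=%s", id)
    writeLines("t,qw,qx,qy,qz", con)
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g",
                       tr$t, tr$qw, tr$qx, tr$qy, tr$qz), con)
  }
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a flat YAML key-value file of run parameters, fills unset keys with
#' defaults, and validates ranges. Keys: `gh_theta` (default 0.9958, the
#' tuned orientation-pipeline value), `theta_bounds` (default `[0.8, 1]`),
#' `offline_cutoff_hz` (2), `input_rate_hz` (100), `upsample_rate_hz`
#' (1000), `rng_seed` (1), `feature_selection` (`"f1"` or `"all"`),
#' `angle_units` (`"radians"` or `"degrees"`), plus the [ga_settings()]
#' fields under `ga:`.
#'
#' @param path YAML file; an empty or absent-key file yields all defaults.
#' @return a list of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- list(gh_theta = 0.9958, theta_bounds = c(0.8, 1),
                   offline_cutoff_hz = 2, input_rate_hz = 100,
                   upsample_rate_hz = 1000, rng_seed = 1L,
                   feature_selection = "f1", angle_units = "radians",
                   ga = list())
  cfg <- modifyList(defaults, raw)
  cfg$theta_bounds <- as.numeric(cfg$theta_bounds)
  if (cfg$gh_theta < 0 || cfg$gh_theta > 1) {
    stop_tremorkin("gh_theta must lie in [0, 1]")
  }
  if (length(cfg$theta_bounds) != 2 ||
      cfg$theta_bounds[1] >= cfg$theta_bounds[2] ||
      cfg$theta_bounds[1] < 0 || cfg$theta_bounds[2] > 1) {
    stop_tremorkin("theta_bounds must be an increasing pair within [0, 1]")
  }
  if (cfg$offline_cutoff_hz >= cfg$input_rate_hz / 2) {
    stop_tremorkin(sprintf(
      "offline_cutoff_hz (%g) must be below the input Nyquist rate (%g Hz)",
      cfg$offline_cutoff_hz, cfg$input_rate_hz / 2))
  }
  if (!cfg$feature_selection %in% c("all", feature_ids())) {
    stop_tremorkin("feature_selection must be 'all' or one of f1..f18")
  }
  cfg$angle_units <- match.arg(cfg$angle_units, c("radians", "degrees"))
  cfg$ga <- do.call(ga_settings, cfg$ga)
  class(cfg) <- "run_config"
  cfg
}

#' Write analysis outputs
#'
#' `write_decomposition_csv()` writes the per-axis decomposition of a joint
#' as one tidy CSV (`channel, t, raw, voluntary, tremor`);
#' `write_run_summary()` writes a JSON run summary.
#'
#' @param dec a `joint_decomposition` from
#'   [estimate_tremor_from_orientation()].
#' @param path output file path.
#' @export
write_decomposition_csv <- function(dec, path) {
  tab <- tidy(dec)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decomposition_csv
#' @param summary named list of run metadata and results.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
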