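#' Tidiers and plots for tremorkin result objects
#'
#' broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods
#' for the package's result types.
#'
#' @param x a tremorkin result object.
#' @param ... ignored.
#' @name tremorkin-tidiers
NULL

#' @rdname tremorkin-tidiers
#' @export
tidy.tremor_decomposition <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), c("raw", "voluntary", "tremor"),
                      names_to = "component", values_to = "value")
}

#' @rdname tremorkin-tidiers
#' @export
glance.tremor_decomposition <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), theta = attr(x, "theta"),
                 n_samples = nrow(x),
                 raw_rms = rms(x$raw), voluntary_rms = rms(x$voluntary),
                 tremor_rms = rms(x$tremor))
}

#' @rdname tremorkin-tidiers
#' @export
tidy.joint_decomposition <- function(x, ...) {
  purrr::imap_dfr(x$axes, function(dec, ch) {
    dplyr::mutate(tibble::as_tibble(dec), channel = ch, .before = 1)
  })
}

#' @rdname tremorkin-tidiers
#' @export
glance.joint_decomposition <- function(x, ...) {
  tibble::tibble(joint = x$joint, theta = x$theta, rate = x$rate,
                 n_samples = nrow(x$axes$x),
                 tremor_rms_norm = rms(x$axes$norm$tremor))
}

#' @rdname tremorkin-tidiers
#' @export
tidy.kte_result <- function(x, ...) {
  tibble::tibble(component = c("kte1", "kte2", "kte"),
                 value = c(x$kte1, x$kte2, x$kte))
}

#' @rdname tremorkin-tidiers
#' @export
glance.kte_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tremorkin-tidiers
#' @export
tidy.location_prediction <- function(x, ...) {
  out <- tibble::tibble(sensor_id = x$predicted_order,
                        predicted_position = seq_along(x$predicted_order))
  if (!is.null(x$per_sensor_correct)) {
    out$correct <- x$per_sensor_correct[out$sensor_id]
  }
  out
}

#' @rdname tremorkin-tidiers
#' @export
glance.location_prediction <- function(x, ...) {
  tibble::tibble(trial_id = x$trial_id, method = x$method,
                 feature_used = x$feature_used, accuracy = x$accuracy,
                 tie = x$tie, conflict = x$conflict)
}

#' @rdname tremorkin-tidiers
#' @export
tidy.ga_result <- function(x, ...) x$trace

#' @rdname tremorkin-tidiers
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(theta = x$theta, fitness = x$fitness,
                 generations = max(x$trace$generation),
                 lower = x$bounds[1], upper = x$bounds[2])
}

#' @rdname tremorkin-tidiers
#' @export
glance.locator_forest <- function(x, ...) {
  tibble::tibble(method = "random_forest", oob_error = x$oob_error,
                 n_trees = x$fit$ntree, n_instances = x$n_instances)
}

#' @rdname tremorkin-tidiers
#' @export
glance.locator_tree <- function(x, ...) {
  tibble::tibble(method = "decision_tree",
                 resubstitution_error = x$resubstitution_error,
                 cv_error = x$cv_error, cp = x$cp)
}

#' @rdname tremorkin-tidiers
#' @param object a result object (autoplot convention).
#' @export
autoplot.tremor_decomposition <- function(object, ...) {
  d <- tidy.tremor_decomposition(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "angular velocity (rad/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tremorkin-tidiers
#' @export
autoplot.joint_decomposition <- function(object, ...) {
  d <- tidy.joint_decomposition(object) |>
    tidyr::pivot_longer(c("raw", "voluntary", "tremor"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angular velocity (rad/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tremorkin-tidiers
#' @export
autoplot.amplitude_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$frequency, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' @rdname tremorkin-tidiers
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness (summed KTE)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-feature ranking accuracy
#'
#' @param accuracies tibble from [evaluate_feature_accuracies()].
#' @return a ggplot object.
#' @export
plot_feature_accuracies <- function(accuracies) {
  d <- dplyr::mutate(accuracies,
                     feature = factor(.data$feature, levels = feature_ids()),
                     highlighted = .data$feature %in% highlighted_features())
  ggplot2::ggplot(d, ggplot2::aes(.data$feature, .data$accuracy,
                                  fill = .data$highlighted)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey65")) +
    ggplot2::labs(x = NULL, y = "ranking accuracy") +
    ggplot2::theme_minimal()
}
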