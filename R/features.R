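#' Per-sensor motion-magnitude features
#'
#' Computes, for every sensor in a trial, the 18 features used to identify
#' relative sensor location on the limb. Each feature summarises one of three
#' derived signals — angular displacement (integrated angular velocity),
#' angular velocity (Poisson equation), angular acceleration — after
#' rectifying each axis (|x|, |y|, |z|), which makes the set invariant to the
#' mounting orientation of the sensor. The features are deliberately
#' magnitude-monotone: on an upper-limb chain both voluntary motion and
#' kinetic tremor grow toward the hand, so larger values indicate a more
#' distal placement.
#'
#' Feature table (D = displacement, V = velocity, A = acceleration):
#' \describe{
#'   \item{f1}{sum over axes of the total path length of rectified D}
#'   \item{f2 / f6 / f10}{sum over axes of per-axis RMS of rectified D/V/A}
#'   \item{f3 / f7 / f11}{RMS of the Euclidean-norm signal of D/V/A}
#'   \item{f4 / f8 / f12}{sum over axes of per-axis population variance of
#'     rectified D/V/A}
#'   \item{f5 / f9}{sum over axes of per-axis maximum of rectified V/A}
#'   \item{f13 / f15 / f17}{sum of the eigenvalues of the 3x3 population
#'     covariance of the rectified axes of D/V/A (equals the trace, hence
#'     f13 = f4, f15 = f8, f17 = f12)}
#'   \item{f14 / f16 / f18}{sum of absolute loadings of the first principal
#'     component of that covariance matrix (absolute values because the
#'     eigenvector sign is arbitrary)}
#' }
#'
#' @param trial a [trial_recording()].
#' @return a tibble with one row per sensor: `sensor_id`, `f1` ... `f18`.
#' @seealso [rank_transform()], [rank_classify()]
#' @export
compute_features <- function(trial) {
  purrr::imap_dfr(trial$sensors, function(tr, id) {
    av <- poisson_angular_velocity(tr)
    disp <- as.matrix(angular_displacement(av)[, c("x", "y", "z")])
    vel <- omega_matrix(av)
    acc <- as.matrix(angular_acceleration(av)[, c("x", "y", "z")])
    dplyr::bind_cols(tibble::tibble(sensor_id = id),
                     feature_vector(disp, vel, acc))
  })
}

feature_vector <- function(disp, vel, acc) {
  rd <- abs(disp); rv <- abs(vel); ra <- abs(acc)
  tibble::tibble(
    f1 = sum(apply(rd, 2, function(x) sum(abs(diff(x))))),
    f2 = sum(apply(rd, 2, rms)),
    f3 = rms(sqrt(rowSums(rd^2))),
    f4 = sum(apply(rd, 2, pop_var)),
    f5 = sum(apply(rv, 2, max)),
    f6 = sum(apply(rv, 2, rms)),
    f7 = rms(sqrt(rowSums(rv^2))),
    f8 = sum(apply(rv, 2, pop_var)),
    f9 = sum(apply(ra, 2, max)),
    f10 = sum(apply(ra, 2, rms)),
    f11 = rms(sqrt(rowSums(ra^2))),
    f12 = sum(apply(ra, 2, pop_var)),
    f13 = cov_eigensum(rd),
    f14 = pc1_loading_sum(rd),
    f15 = cov_eigensum(rv),
    f16 = pc1_loading_sum(rv),
    f17 = cov_eigensum(ra),
    f18 = pc1_loading_sum(ra)
  )
}

rms <- function(x) sqrt(mean(x^2))

pop_var <- function(x) mean((x - mean(x))^2)

pop_cov <- function(m) {
  centered <- sweep(m, 2, colMeans(m))
  crossprod(centered) / nrow(m)
}

cov_eigensum <- function(m) sum(diag(pop_cov(m)))

pc1_loading_sum <- function(m) {
  cv <- pop_cov(m)
  if (max(abs(cv)) < 1e-300) {
    rlang::warn("degenerate (constant) signal: first principal component set by tie-break")
    return(1)  # canonical axis chosen by eigen() on the zero matrix
  }
  ev <- eigen(cv, symmetric = TRUE)
  sum(abs(ev$vectors[, 1]))
}

#' Rank sensors within each feature
#'
#' Converts a per-sensor feature table into within-feature ranks: for every
#' feature, sensors are ranked by descending value, rank 1 = largest. Using
#' ranks instead of raw magnitudes makes the downstream classifiers robust
#' across tremor intensities, which rescale all features together. Ties are
#' broken by sensor input order and flagged.
#'
#' @param features tibble as returned by [compute_features()] (at least two
#'   sensors).
#' @return a long tibble with columns `feature` (`"f1"`...`"f18"`),
#'   `sensor_id`, `value`, `rank`, `tie` (logical).
#' @export
rank_transform <- function(features) {
  if (nrow(features) < 2) {
    stop_tremorkin("ranking needs at least 2 sensors")
  }
  long <- tidyr::pivot_longer(features, -"sensor_id",
                              names_to = "feature", values_to = "value")
  long |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(
      rank = rank_descending(.data$value),
      tie = anyDuplicated(.data$value) > 0
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$feature, feature_ids()),
                   .data$rank)
}

# descending rank, ties broken by input (first-come) order
rank_descending <- function(x) {
  ord <- order(-x)  # stable sort: earlier index wins ties
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

feature_ids <- function() paste0("f", 1:18)

#' @rdname rank_transform
#' @return `highlighted_features()` returns the ids of the features that are
#'   strictly monotone in motion magnitude along the chain and therefore
#'   reach full ranking accuracy on clean chains.
#' @export
highlighted_features <- function() {
  paste0("f", c(1, 2, 4, 5, 6, 7, 8, 13, 15))
}
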