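#' Training-free sensor-location identification by ranking
#'
#' Sorts a trial's sensors by descending value of one magnitude-monotone
#' feature: because every joint adds motion on top of the proximal segments,
#' the largest value is predicted to sit most distally (position 1 = hand).
#' Ranking needs no training, so the sensor chain can be shortened, extended
#' or slid without refitting anything — the only requirement is knowing which
#' configuration is worn. Ties are broken by sensor input order and flagged.
#'
#' @param trial a [trial_recording()].
#' @param feature_id feature to rank on, `"f1"`...`"f18"` (or bare integer
#'   1-18). Feature 1 (summed total angular path of displacement) is the
#'   canonical choice.
#' @param features optional precomputed [compute_features()] table for this
#'   trial, to avoid recomputation.
#' @return a list of class `location_prediction`: `predicted_order` (sensor
#'   ids distal to proximal), `per_sensor_correct` (named logical, against
#'   the trial's true locations), `accuracy`, `method`, `feature_used`,
#'   `tie`.
#' @examples
#' trial <- simulate_trial(synth_config(seed = 3))
#' rank_classify(trial, "f1")$accuracy
#' @export
rank_classify <- function(trial, feature_id = "f1", features = NULL) {
  feature_id <- normalize_feature_id(feature_id)
  if (is.null(features)) features <- compute_features(trial)
  vals <- features[[feature_id]]
  ord <- order(-vals)
  predicted_order <- features$sensor_id[ord]
  tie <- anyDuplicated(vals) > 0
  new_location_prediction(trial, predicted_order, method = "ranking",
                          feature_used = feature_id, tie = tie)
}

normalize_feature_id <- function(feature_id) {
  if (is.numeric(feature_id)) feature_id <- paste0("f", feature_id)
  if (!feature_id %in% feature_ids()) {
    stop_tremorkin(sprintf("unknown feature id '%s'", feature_id))
  }
  feature_id
}

new_location_prediction <- function(trial, predicted_order, method,
                                    feature_used, tie = FALSE,
                                    conflict = FALSE) {
  predicted_pos <- stats::setNames(seq_along(predicted_order),
                                   predicted_order)
  truth <- trial$true_locations
  per_sensor_correct <- NULL
  accuracy <- NA_real_
  if (!is.null(truth)) {
    per_sensor_correct <- predicted_pos[names(truth)] == truth
    names(per_sensor_correct) <- names(truth)
    accuracy <- mean(per_sensor_correct)
  }
  structure(list(predicted_order = predicted_order,
                 per_sensor_correct = per_sensor_correct,
                 accuracy = accuracy, method = method,
                 feature_used = feature_used, tie = tie,
                 conflict = conflict, trial_id = trial$trial_id),
            class = "location_prediction")
}

#' @export
print.location_prediction <- function(x, ...) {
  cat(sprintf("<location_prediction %s (%s)>\n", x$method, x$feature_used))
  cat("  predicted (distal to proximal):",
      paste(x$predicted_order, collapse = " > "), "\n")
  if (!is.na(x$accuracy)) cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  if (x$tie) cat("  note: tie broken by input order\n")
  if (x$conflict) cat("  note: label conflict resolved by confidence\n")
  invisible(x)
}

#' Ranking accuracy of every feature over a trial collection
#'
#' Pools, per feature, the fraction of sensor placements identified
#' correctly by [rank_classify()] across all trials. All trials must share
#' the sensor configuration and carry true locations.
#'
#' @param trials list of [trial_recording()]s with known true locations.
#' @return a tibble `feature`, `accuracy`, `n_placements` sorted by the
#'   feature index.
#' @export
evaluate_feature_accuracies <- function(trials) {
  if (length(trials) == 0) stop_tremorkin("empty trial collection")
  confs <- unique(vapply(trials, `[[`, "", "configuration"))
  if (length(confs) != 1) {
    stop_tremorkin("all trials must share one sensor configuration")
  }
  feats <- lapply(trials, compute_features)
  purrr::map_dfr(feature_ids(), function(f) {
    correct <- unlist(lapply(seq_along(trials), function(i) {
      rank_classify(trials[[i]], f, features = feats[[i]])$per_sensor_correct
    }))
    tibble::tibble(feature = f, accuracy = mean(correct),
                   n_placements = length(correct))
  })
}

#' Build a classifier instance table from trials
#'
#' One row per (trial, sensor): the sensor's 18 within-trial feature ranks
#' as predictors and its true chain ordinal as the label.
#'
#' @param trials list of [trial_recording()]s with true locations.
#' @return tibble with `trial_id`, `sensor_id`, `location` (factor of chain
#'   ordinals) and rank predictors `f1`...`f18`.
#' @export
feature_rank_table <- function(trials) {
  purrr::map_dfr(trials, function(trial) {
    ranks <- rank_transform(compute_features(trial)) |>
      dplyr::select("feature", "sensor_id", "rank") |>
      tidyr::pivot_wider(names_from = "feature", values_from = "rank")
    ranks$location <- trial$true_locations[ranks$sensor_id]
    dplyr::mutate(ranks, trial_id = trial$trial_id, .before = 1)
  }) |>
    dplyr::mutate(location = factor(.data$location))
}

#' Random-forest sensor-location classifier
#'
#' Bagged ensemble of trees on the rank features: 100 trees, minimum leaf
#' size 4, sqrt(n features) candidates per split, with the out-of-bag error
#' (error on instances excluded from each bootstrap) as the built-in
#' generalization estimate.
#'
#' @param feature_table tibble from [feature_rank_table()] (or any tibble
#'   with `f1`...`f18` predictor columns and a `location` factor).
#' @param n_trees number of trees (default 100).
#' @param min_leaf minimum node size (default 4).
#' @param seed integer seed for the bootstrap and split randomness.
#' @return a list of class `locator_forest`: `fit` (randomForest object),
#'   `oob_error`, `n_instances`.
#' @export
train_random_forest <- function(feature_table, n_trees = 100, min_leaf = 4,
                                seed = 1L) {
  check_instance_table(feature_table)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  x <- as.data.frame(feature_table[, feature_ids()])
  yl <- droplevels(feature_table$location)
  fit <- randomForest::randomForest(
    x = x, y = yl, ntree = n_trees, nodesize = min_leaf,
    mtry = floor(sqrt(length(feature_ids()))))
  oob <- mean(fit$predicted != yl)
  structure(list(fit = fit, oob_error = oob,
                 n_instances = nrow(feature_table)),
            class = "locator_forest")
}

#' Pruned decision-tree sensor-location classifier
#'
#' Single classification tree on the rank features with cost-complexity
#' pruning selected by the one-standard-deviation rule: grow the full tree,
#' estimate the error of each pruning level by `n_folds`-fold
#' cross-validation, and keep the smallest subtree whose CV error is within
#' one standard deviation of the minimum — guarding against an over-fitted
#' sub-optimum. Both the resubstitution error (training-set error, which
#' only decreases with tree size) and the CV error of the kept subtree are
#' reported.
#'
#' @inheritParams train_random_forest
#' @param n_folds cross-validation folds (default 10).
#' @return a list of class `locator_tree`: `fit` (pruned rpart object),
#'   `resubstitution_error`, `cv_error`, `cp` (complexity used).
#' @export
train_decision_tree <- function(feature_table, n_folds = 10, seed = 1L) {
  check_instance_table(feature_table)
  if (n_folds > nrow(feature_table)) {
    stop_tremorkin("more CV folds than instances")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  df <- as.data.frame(feature_table[, c(feature_ids(), "location")])
  df$location <- droplevels(df$location)
  fit <- rpart::rpart(location ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        xval = n_folds, cp = 0, minsplit = 2, minbucket = 1))
  cp <- fit$cptable
  best <- which.min(cp[, "xerror"])
  thresh <- cp[best, "xerror"] + cp[best, "xstd"]
  keep <- which(cp[, "xerror"] <= thresh)[1]  # smallest tree within 1 SD
  pruned <- rpart::prune(fit, cp = cp[keep, "CP"])
  root_err <- mean(df$location != names(which.max(table(df$location))))
  resub <- mean(predict(pruned, df, type = "class") != df$location)
  # rpart's xerror is relative to the root-node (modal-class) error
  cv_err <- cp[keep, "xerror"] * root_err
  structure(list(fit = pruned, resubstitution_error = resub,
                 cv_error = cv_err, cp = cp[keep, "CP"]),
            class = "locator_tree")
}

check_instance_table <- function(feature_table) {
  missing <- setdiff(c(feature_ids(), "location"), names(feature_table))
  if (length(missing) > 0) {
    stop_tremorkin(paste0("instance table lacks columns: ",
                          paste(missing, collapse = ", ")))
  }
  yl <- droplevels(factor(feature_table$location))
  if (nlevels(yl) < 2) {
    stop_tremorkin("labels contain a single class; model would be degenerate")
  }
  invisible(feature_table)
}

#' Classify a trial's sensors with a fitted locator model
#'
#' Predicts each sensor's chain ordinal from its rank features. If two
#' sensors in the trial receive the same ordinal, the higher-confidence
#' sensor keeps it and the other is moved to its best still-free label; the
#' conflict is flagged on the prediction.
#'
#' @param model a `locator_forest` or `locator_tree`.
#' @param trial a [trial_recording()].
#' @return a `location_prediction` (see [rank_classify()]).
#' @export
classify_trial <- function(model, trial) {
  ranks <- rank_transform(compute_features(trial)) |>
    dplyr::select("feature", "sensor_id", "rank") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "rank")
  x <- as.data.frame(ranks[, feature_ids()])
  fit <- model$fit
  prob <- predict(fit, x, type = "prob")
  labels <- as.integer(colnames(prob))
  n <- nrow(x)
  assigned <- integer(n)
  conflict <- FALSE
  # greedy by confidence: highest posterior first, next-best if taken
  remaining <- seq_len(n)
  taken <- integer(0)
  argmax <- apply(prob, 1, which.max)
  if (anyDuplicated(labels[argmax]) > 0) conflict <- TRUE
  while (length(remaining) > 0) {
    conf <- vapply(remaining, function(i) {
      free <- setdiff(seq_along(labels), taken)
      max(prob[i, free])
    }, numeric(1))
    i <- remaining[which.max(conf)]
    free <- setdiff(seq_along(labels), taken)
    j <- free[which.max(prob[i, free])]
    assigned[i] <- labels[j]
    taken <- c(taken, j)
    remaining <- setdiff(remaining, i)
  }
  predicted_order <- ranks$sensor_id[order(assigned)]
  method <- if (inherits(model, "locator_forest")) "random_forest"
            else "decision_tree"
  new_location_prediction(trial, predicted_order, method = method,
                          feature_used = "model", conflict = conflict)
}
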