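# trial with directly prescribed feature magnitudes via per-sensor omega
scaled_trial <- function(scales, t = seq(0, 6, by = 0.01)) {
  om <- cbind(sin(2 * pi * 0.4 * t), 0.5 * sin(2 * pi * 0.6 * t),
              0.4 * cos(2 * pi * 0.3 * t))
  sensors <- lapply(scales, function(s) {
    integrate_orientation(angvel_trace(t, om * s))
  })
  trial_recording("scaled", "three_mimu_distal", sensors,
                  reference_order = names(scales), sample_rate = 100)
}

test_that("consistent feature ordering gives perfect placement", {
  trial <- scaled_trial(c(hand = 1, forearm = 0.6, humerus = 0.2))
  pred <- rank_classify(trial, "f1")
  expect_equal(pred$predicted_order, c("hand", "forearm", "humerus"))
  expect_equal(pred$accuracy, 1)
  expect_false(pred$tie)
})

test_that("reversed feature ordering leaves only the middle sensor correct", {
  trial <- scaled_trial(c(hand = 0.2, forearm = 0.6, humerus = 1))
  pred <- rank_classify(trial, "f1")
  expect_equal(pred$predicted_order, c("humerus", "forearm", "hand"))
  expect_equal(unname(pred$per_sensor_correct[c("hand", "forearm", "humerus")]),
               c(FALSE, TRUE, FALSE))
  expect_equal(pred$accuracy, 1 / 3)
})

test_that("ties are broken by input order and flagged", {
  trial <- scaled_trial(c(a = 0.5, b = 0.5, c = 0.5))
  pred <- rank_classify(trial, "f1")
  expect_true(pred$tie)
  expect_equal(pred$predicted_order, c("a", "b", "c"))
  expect_error(rank_classify(trial, "f99"), "unknown feature")
})

test_that("ranking is invariant to the order sensors appear in the trial", {
  trial <- simulate_trial(quick_config(seed = 44))
  shuffled <- trial
  perm <- c(2, 3, 1)
  shuffled$sensors <- trial$sensors[perm]
  pred1 <- rank_classify(trial, "f1")
  pred2 <- rank_classify(shuffled, "f1")
  expect_equal(pred1$predicted_order, pred2$predicted_order)
  expect_equal(pred1$accuracy, pred2$accuracy)
})

test_that("per-feature accuracies pool placements over trials", {
  suite <- lapply(c(3, 5), function(s) simulate_trial(quick_config(seed = s)))
  acc <- evaluate_feature_accuracies(suite)
  expect_equal(nrow(acc), 18)
  expect_true(all(acc$n_placements == 6))
  hi <- dplyr::filter(acc, feature %in% highlighted_features())
  expect_true(all(hi$accuracy == 1))
  # redundancy: the two path/RMS displacement features agree
  expect_equal(acc$accuracy[acc$feature == "f1"],
               acc$accuracy[acc$feature == "f2"])
  expect_error(evaluate_feature_accuracies(list()), "empty")
})

test_that("random forest separates a deterministic rank table and reports OOB error", {
  tab <- separable_rank_table(per_class = 15)
  fit <- train_random_forest(tab, seed = 7)
  expect_lte(fit$oob_error, 0.05)
  expect_equal(fit$fit$ntree, 100)
  expect_error(train_random_forest(dplyr::mutate(tab, location = factor(1))),
               "single class")
})

test_that("permuted labels drop the forest to chance-level accuracy", {
  tab <- separable_rank_table(per_class = 15)
  accs <- vapply(1:10, function(seed) {
    set.seed(1000 + seed)
    shuffled <- dplyr::mutate(tab, location = sample(location))
    1 - train_random_forest(shuffled, seed = seed)$oob_error
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("duplicating instances leaves the OOB estimate stable", {
  tab <- separable_rank_table(per_class = 15)
  doubled <- tab[rep(seq_len(nrow(tab)), 2), ]
  e1 <- train_random_forest(tab, seed = 3)$oob_error
  e2 <- train_random_forest(doubled, seed = 3)$oob_error
  expect_lt(abs(e1 - e2), 0.05)
})

test_that("decision tree achieves zero resubstitution error when separable", {
  tab <- separable_rank_table(per_class = 8)
  fit <- train_decision_tree(tab, seed = 2)
  expect_equal(fit$resubstitution_error, 0)
  expect_error(train_decision_tree(tab[c(1:4, 16:19), ], n_folds = 10),
               "folds")
})

test_that("resubstitution error never exceeds cross-validation error", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    loc <- sample(1:3, n, replace = TRUE)
    ranks <- sapply(1:18, function(j) {
      pmin(3, pmax(1, loc + sample(c(-1, 0, 0, 0, 1), n, replace = TRUE)))
    })
    colnames(ranks) <- paste0("f", 1:18)
    tab <- dplyr::bind_cols(tibble::as_tibble(ranks),
                            tibble::tibble(location = factor(loc)))
    fit <- train_decision_tree(tab, seed = seed)
    expect_lte(fit$resubstitution_error, fit$cv_error + 1e-12)
  }
})

test_that("constant features prune to a single modal leaf", {
  tab <- separable_rank_table(per_class = 10)
  tab[paste0("f", 1:18)] <- 1
  tab$location <- factor(c(rep(1, 18), rep(2, 6), rep(3, 6)))
  fit <- train_decision_tree(tab, seed = 1)
  expect_equal(nrow(fit$fit$frame), 1)  # a lone leaf
  pred <- predict(fit$fit, as.data.frame(tab), type = "class")
  expect_true(all(pred == "1"))
})

test_that("fitted models classify trials and resolve label conflicts", {
  train <- make_fixture_suite(9, template = quick_config(seed = 1), seed = 5)
  held_out <- make_fixture_suite(4, template = quick_config(seed = 1), seed = 6)
  tab <- feature_rank_table(train)
  forest <- train_random_forest(tab, seed = 11)
  accs <- vapply(held_out, function(tr) classify_trial(forest, tr)$accuracy,
                 numeric(1))
  expect_gte(mean(accs), (1 - forest$oob_error) - 0.1)

  # a training trial classified by its own separable model gets its labels
  pred <- classify_trial(forest, train[[1]])
  expect_equal(pred$accuracy, 1)
  expect_equal(pred$method, "random_forest")
})

test_that("ranking is stateless: predictions survive serialization", {
  trial <- simulate_trial(quick_config(seed = 50))
  pred1 <- rank_classify(trial, "f5")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(trial, path)
  pred2 <- rank_classify(read_trial(path), "f5")
  expect_equal(pred1$predicted_order, pred2$predicted_order)
  expect_equal(pred1$accuracy, pred2$accuracy)
})
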