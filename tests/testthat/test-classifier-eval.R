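test_that("linear margin fit separates and respects sign symmetries", {
  x <- rbind(c(-1, 0), c(1, 0))
  y <- c("neg", "pos")
  m <- fit_linear_margin(x, y, C = 100, positive_class = "pos")
  expect_identical(unname(predict(m, x)), c("neg", "pos"))
  # symmetric points -> boundary at the midpoint
  expect_lt(abs(decision_scores(m, matrix(c(0, 0), 1))), 1e-6)
  # duplicating every sample leaves the optimum unchanged
  m2 <- fit_linear_margin(rbind(x, x), rep(y, 2), C = 100,
                          positive_class = "pos")
  expect_equal(m2$weights, m$weights, tolerance = 1e-6)
  expect_equal(m2$bias, m$bias, tolerance = 1e-6)
  # flipping the positive class negates the decision function
  m3 <- fit_linear_margin(x, y, C = 100, positive_class = "neg")
  expect_equal(m3$weights, -m$weights, tolerance = 1e-6)
  expect_equal(m3$bias, -m$bias, tolerance = 1e-6)
  expect_error(fit_linear_margin(x, c("pos", "pos"), C = 1,
                                 positive_class = "pos"), "2 classes")
  # orientation must not depend on which class appears first in the data
  set.seed(20)
  xx <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(40, -2), 20))
  yy <- rep(c("u", "p"), each = 20)
  mp <- fit_linear_margin(xx, yy, C = 1, positive_class = "p")
  expect_gt(mean(decision_scores(mp, xx[yy == "p", , drop = FALSE])), 0)
  expect_lt(mean(decision_scores(mp, xx[yy == "u", , drop = FALSE])), 0)
})

test_that("penalty grid search maximizes CV accuracy with smallest-C ties", {
  set.seed(21)
  x <- rbind(matrix(rnorm(60, 3), 30, 2), matrix(rnorm(60, -3), 30, 2))
  y <- rep(c("pos", "neg"), each = 30)
  cfg1 <- classifier_config(penalty_grid = 7, n_folds = 5,
                            positive_class = "pos", rng_seed = 1)
  expect_equal(grid_search_penalty(x, y, cfg1), 7)
  # separable problem: every C ties -> smallest returned
  cfg2 <- classifier_config(penalty_grid = c(0.1, 1, 10), n_folds = 5,
                            positive_class = "pos", rng_seed = 1)
  expect_equal(grid_search_penalty(x, y, cfg2), 0.1)
  # chosen C really is an argmax over the grid (exhaustive check)
  set.seed(22)
  xn <- matrix(rnorm(80 * 5), 80)
  xn[, 1] <- xn[, 1] + rep(c(0, 1.2), each = 40)
  yn <- rep(c("a", "b"), each = 40)
  cfg3 <- classifier_config(penalty_grid = 10^(-2:2), n_folds = 4,
                            positive_class = "b", rng_seed = 3)
  chosen <- grid_search_penalty(xn, yn, cfg3)
  accs <- vapply(cfg3$penalty_grid, function(C) {
    folds <- make_stratified_folds(yn, 4, 3)
    mean(vapply(1:4, function(f) {
      m <- fit_linear_margin(xn[folds != f, ], yn[folds != f], C, "b")
      mean(predict(m, xn[folds == f, ]) == yn[folds == f])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(accs[match(chosen, cfg3$penalty_grid)], max(accs))
})

test_that("stratified folds partition subjects and preserve proportions", {
  y <- rep(c("UD", "BD"), times = c(50, 48))
  folds <- make_stratified_folds(y, 8, rng_seed = 4)
  expect_length(folds, 98L)
  sizes <- sort(unname(table(folds)))
  expect_equal(sizes, c(rep(12L, 6), rep(13L, 2)), ignore_attr = TRUE)
  # each fold holds 6-7 of each class
  per_class <- table(folds, y)
  expect_true(all(per_class >= 6 & per_class <= 7))
  expect_error(make_stratified_folds(rep(c("a", "b"), c(3, 50)), 8),
               "at least k")
})

test_that("cross-validated evaluation is exact on separable data, chance on null", {
  set.seed(23)
  x <- rbind(matrix(rnorm(80, 4), 40, 2), matrix(rnorm(80, -4), 40, 2))
  y <- rep(c("pos", "neg"), each = 40)
  cfg <- classifier_config(n_folds = 8, positive_class = "pos", rng_seed = 5)
  ev <- stratified_kfold_eval(x, y, cfg)
  expect_equal(ev$mean_accuracy, 1)
  expect_equal(ev$auc, 1)
  # every subject appears in exactly one test fold
  expect_equal(sort(unique(ev$folds)), 1:8)
  expect_length(ev$folds, 80L)
  # null labels: accuracy near chance averaged over seeds
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    xn <- matrix(rnorm(40 * 10), 40)
    yn <- sample(rep(c("pos", "neg"), each = 20))
    cfg_n <- classifier_config(n_folds = 4, positive_class = "pos",
                               rng_seed = s)
    stratified_kfold_eval(xn, yn, cfg_n)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("confusion metrics reproduce the canonical holdout composition", {
  # 23 positive (4 missed), 19 negative (4 false alarms)
  labels <- rep(c("tBD", "UD"), times = c(23, 19))
  preds <- c(rep("tBD", 19), rep("UD", 4), rep("UD", 15), rep("tBD", 4))
  cm <- confusion_metrics(preds, labels, "tBD")
  expect_equal(cm$accuracy, 34 / 42, tolerance = 1e-12)
  expect_equal(round(cm$accuracy, 4), 0.8095)
  expect_equal(round(cm$sensitivity, 4), 0.8261)
  expect_equal(round(cm$specificity, 4), 0.7895)
  expect_equal(confusion_metrics(labels, labels, "tBD"),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  flipped <- ifelse(labels == "tBD", "UD", "tBD")
  cm0 <- confusion_metrics(flipped, labels, "tBD")
  expect_equal(unlist(cm0), c(accuracy = 0, sensitivity = 0,
                              specificity = 0))
  expect_error(confusion_metrics(preds, rep("tBD", 42), "tBD"),
               "both positive and negative")
})

test_that("ROC/AUC matches the pairwise win-probability estimator", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c("p", "p", "n", "n"), "p")$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("p", "n"), 5), "p")$auc, 0.5)
  ex <- roc_auc(c(0.9, 0.8, 0.85, 0.1), c("p", "p", "n", "n"), "p")
  expect_equal(ex$auc, 0.75)
  set.seed(24)
  for (i in 1:15) {
    n <- sample(6:50, 1)
    labels <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("p", "n")
    scores <- round(rnorm(n), 1)   # ties likely
    got <- roc_auc(scores, labels, "p")
    expect_equal(got$auc, oracle_auc(scores, labels, "p"),
                 tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(unlist(got$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(got$roc_points[nrow(got$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(got$roc_points$fpr) >= 0))
    expect_true(all(diff(got$roc_points$tpr) >= 0))
  }
})

test_that("holdout evaluation never refits and checks the feature space", {
  spec <- small_train_spec(rng_seed = 41)
  co <- simulate_cohort(spec)
  ft <- build_feature_matrix(co$runs, co$atlas)
  clf <- train_classifier(ft$values, co$subjects$group, ft$registry,
                          selection_config(rng_seed = 41),
                          classifier_config(penalty_grid = c(0.1, 1),
                                            n_folds = 4, rng_seed = 41))
  ev <- holdout_test(clf, ft$values, co$subjects$group, ft$registry)
  expect_gte(ev$mean_accuracy, 0.9)   # training sample, separable signal
  # converted-bipolar holdout scored against the bipolar-trained model
  spec_te <- cohort_spec(grid_shape = spec$grid_shape, n_regions = 6,
                         seed_region_ids = 1L, planted_region_ids = c(3, 5),
                         n_per_group = c(UD = 8L, tBD = 8L),
                         n_timepoints = 120L, rng_seed = 141)
  te <- simulate_cohort(spec_te, co$atlas)
  ft_te <- build_feature_matrix(te$runs, co$atlas)
  ev_te <- holdout_test(clf, ft_te$values, te$subjects$group, ft_te$registry,
                        positive_class = "tBD")
  expect_gte(ev_te$mean_accuracy, 0.8)
  # registry mismatch -> error
  bad_reg <- ft$registry
  bad_reg$region <- rev(bad_reg$region)
  expect_error(holdout_test(clf, ft$values, co$subjects$group, bad_reg),
               "mismatch")
})

test_that("permutation p follows the add-one formula and is monotone", {
  # hook that scores the true labelling above every permutation
  y_obs <- rep(c("a", "b"), each = 6)
  hook_top <- function(values, labels) mean(labels == y_obs)
  cfg <- classifier_config(n_folds = 2, positive_class = "b", rng_seed = 9,
                           n_permutations = 200)
  x <- matrix(0, 12, 1)
  res <- permutation_significance(x, y_obs, cfg, hook_top)
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$observed, 1)
  # a hook whose observed value sits at the null median gives p near 0.5
  hook_const_obs <- local({
    first <- TRUE
    function(values, labels) {
      if (first) { first <<- FALSE; return(0.5) }
      runif(1)
    }
  })
  res2 <- permutation_significance(x, y_obs, cfg, hook_const_obs)
  expect_gt(res2$p_value, 0.3)
  expect_lt(res2$p_value, 0.7)
  # p bounds
  expect_gte(res$p_value, 1 / (cfg$n_permutations + 1))
  expect_lte(res2$p_value, 1)
})

test_that("evaluation reports are reproducible under fixed seeds", {
  spec <- small_train_spec(rng_seed = 51)
  co <- simulate_cohort(spec)
  ft <- build_feature_matrix(co$runs, co$atlas)
  cfg <- classifier_config(n_folds = 4, rng_seed = 51)
  hook <- selection_hook(ft$registry, selection_config(rng_seed = 51,
                                                       n_trees = 50))
  e1 <- stratified_kfold_eval(ft$values, co$subjects$group, cfg, hook)
  e2 <- stratified_kfold_eval(ft$values, co$subjects$group, cfg, hook)
  expect_identical(e1$per_fold, e2$per_fold)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$auc, e2$auc)
})
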