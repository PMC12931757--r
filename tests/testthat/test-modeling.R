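make_signal_cohort <- function(n = 400L, p_inf = 3L, p_noise = 3L,
                               seed = 1L, beta = 2) {
  set.seed(seed)
  p <- p_inf + p_noise
  X <- matrix(rnorm(n * p), n)
  eta <- X[, seq_len(p_inf), drop = FALSE] %*% rep(beta, p_inf)
  y <- as.numeric(runif(n) < plogis(eta))
  sch <- toy_schema(p, 0)
  vals <- as.data.frame(X)
  names(vals) <- paste0("v", seq_len(p))
  vals$y <- y
  cohort_table(vals, sch)
}

test_that("train/test split is stratified, disjoint and seeded", {
  sch <- toy_schema(1, 0)
  vals <- data.frame(v1 = rnorm(1000), y = rep(c(0, 1), each = 500))
  ct <- cohort_table(vals, sch)
  sp <- split_train_test(ct, 0.8, seed = 1)
  expect_equal(nrow(sp$train$values), 800L)
  expect_equal(sum(sp$train$values$y), 400)
  expect_length(intersect(sp$train$record_ids, sp$test$record_ids), 0L)
  expect_setequal(c(sp$train$record_ids, sp$test$record_ids),
                  ct$record_ids)
  sp2 <- split_train_test(ct, 0.8, seed = 1)
  expect_identical(sp$train$record_ids, sp2$train$record_ids)
})

test_that("grid search returns the singleton and produces a full trace", {
  ct <- make_signal_cohort(n = 200, seed = 2)
  single <- list(list(maxdepth = 4))
  res <- tune_classifier(ct, "decision_tree", grid = single, folds = 3,
                         seed = 1)
  expect_identical(res$best_params, single[[1]])
  grid <- lapply(c(2, 4, 8), function(d) list(maxdepth = d))
  res3 <- tune_classifier(ct, "decision_tree", grid = grid, folds = 3,
                          seed = 1)
  expect_equal(nrow(res3$trace), length(grid) * 3L)
})

test_that("select-k-best keeps the informative features and the identity at k = all", {
  ct <- make_signal_cohort(n = 500, seed = 3)
  sel_all <- select_features(ct, "select_k_best", "logistic_regression",
                             params = list(k_grid = 6, folds = 3),
                             seed = 1)
  expect_setequal(sel_all$selected, paste0("v", 1:6))
  sel <- select_features(ct, "select_k_best", "logistic_regression",
                         params = list(k_grid = 3, folds = 3), seed = 1)
  expect_setequal(sel$selected, c("v1", "v2", "v3"))
  expect_error(select_features(ct, "select_k_best",
                               params = list(k_grid = 10)),
               "exceeds")
})

test_that("PCA selection tunes the component count and transforms consistently", {
  ct <- make_signal_cohort(n = 300, seed = 4)
  sel <- select_features(ct, "pca", "logistic_regression",
                         params = list(component_grid = c(2, 4, 6),
                                       folds = 3), seed = 1)
  expect_lte(sel$n_components, 6L)
  Xt <- apply_selection(sel, ct)
  expect_equal(ncol(Xt), sel$n_components)
  expect_equal(nrow(sel$trace), 3L)
})

test_that("recursive elimination drops noise before signal", {
  ct <- make_signal_cohort(n = 400, p_inf = 2, p_noise = 4, seed = 5,
                           beta = 3)
  sel <- select_features(ct, "rfecv", "logistic_regression",
                         params = list(folds = 3), seed = 1)
  expect_true(all(c("v1", "v2") %in% sel$selected))
})

test_that("the Taguchi array drives exactly nine GA tuning runs", {
  arr <- taguchi_l9()
  expect_equal(dim(arr), c(9L, 3L))
  for (j in 1:3) expect_setequal(unique(arr[, j]), 1:3)
  # each factor-pair sees all 9 level combinations exactly once
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(nrow(unique(arr[, c(a, b)])), 9L)
  }
  ct <- make_signal_cohort(n = 150, p_inf = 2, p_noise = 2, seed = 6)
  cfg <- ga_config(n_generations = 3, stagnation = 2,
                   taguchi_levels = list(population_size = c(4L, 6L, 8L),
                                         crossover_rate = c(0.6, 0.8,
                                                            0.9),
                                         mutation_rate = c(0.01, 0.05,
                                                           0.1)))
  sel <- select_features(ct, "genetic_algorithm", "logistic_regression",
                         params = list(ga = cfg, folds = 3), seed = 1)
  expect_equal(nrow(sel$trace), 9L)
  expect_gte(length(sel$selected), 1L)
})

test_that("evaluation reports coherent per-fold metrics, CIs and test metrics", {
  ct <- make_signal_cohort(n = 500, seed = 7, beta = 4)
  sp <- split_train_test(ct, 0.8, seed = 1)
  rep_ <- evaluate_model(sp$train, sp$test, "logistic_regression",
                         folds = 5, seeds = 1:2)
  expect_equal(nrow(rep_$per_fold), 10L)
  # F1 is the harmonic mean of precision and recall, fold by fold
  with(rep_$per_fold, {
    h <- ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0)
    expect_equal(f1, h, tolerance = 1e-12)
  })
  pooled <- rep_$pooled
  expect_true(all(pooled$ci_low <= pooled$mean &
                    pooled$mean <= pooled$ci_high))
  expect_true(all(rep_$test_metrics >= 0 & rep_$test_metrics <= 1))
  expect_equal(sum(rep_$importance), 1, tolerance = 1e-12)
})

test_that("perfectly separable data yields perfect fold metrics and zero-width CI", {
  sch <- toy_schema(1, 0)
  vals <- data.frame(v1 = c(rnorm(100, -8), rnorm(100, 8)),
                     y = rep(c(0, 1), each = 100))
  ct <- cohort_table(vals, sch)
  sp <- split_train_test(ct, 0.8, seed = 2)
  rep_ <- evaluate_model(sp$train, sp$test, "decision_tree",
                         params = list(maxdepth = 2), folds = 5,
                         seeds = 1)
  expect_true(all(rep_$per_fold$accuracy == 1))
  acc <- rep_$pooled[rep_$pooled$metric == "accuracy", ]
  expect_equal(acc$ci_low, acc$ci_high)
  expect_equal(rep_$test_metrics[["auc"]], 1)
})

test_that("feature selection ignores the held-out test rows", {
  ct <- make_signal_cohort(n = 400, seed = 8)
  sp <- split_train_test(ct, 0.8, seed = 3)
  sel1 <- select_features(sp$train, "select_k_best",
                          "logistic_regression",
                          params = list(k_grid = 3, folds = 3), seed = 5)
  noise <- sp$test
  noise$values[paste0("v", 1:6)] <-
    as.data.frame(matrix(rnorm(nrow(noise$values) * 6),
                         nrow(noise$values)))
  sel2 <- select_features(sp$train, "select_k_best",
                          "logistic_regression",
                          params = list(k_grid = 3, folds = 3), seed = 5)
  expect_identical(sel1$selected, sel2$selected)
})

test_that("importance aggregation averages the top models with name-order ties", {
  mk <- function(id, imp, acc) {
    structure(list(classifier_id = id,
                   importance = imp,
                   pooled = data.frame(metric = "accuracy", mean = acc)),
              class = "model_report")
  }
  f <- c(a = 0, b = 0, c = 0)
  r1 <- mk("m1", c(a = 1, b = 0, c = 0), 0.9)
  r2 <- mk("m2", c(a = 0, b = 1, c = 0), 0.8)
  r3 <- mk("m3", c(a = 0, b = 0, c = 1), 0.7)
  r4 <- mk("m4", NULL, 0.95)
  agg <- aggregate_importance(list(r1, r2, r3, r4), k = 3, top_n = 3)
  expect_equal(agg$mean_importance, rep(1 / 3, 3))
  expect_equal(agg$feature, c("a", "b", "c"))   # ties by name order
  expect_true("m4" %in% attr(agg, "excluded"))
  same <- aggregate_importance(list(r1, r1, r1), k = 3, top_n = 2)
  expect_equal(same$mean_importance, c(1, 0, 0))
  expect_equal(sum(same$top), 2L)
})

test_that("ensemble models outperform plain k-NN on a calibrated cohort", {
  ct <- generate_cohort(cohort_sim_config(n_records = 900, seed = 19))
  X <- mafldml:::feature_matrix(ct)
  y <- ct$values$mafld
  knn <- cv_grid_search("k_nearest_neighbors", X, y,
                        grid = list(list(k = 5)), folds = 3, seed = 1,
                        metric = "accuracy")
  xgb <- cv_grid_search("extreme_gradient_boosting", X, y,
                        grid = list(list(max_depth = 3, nrounds = 100)),
                        folds = 3, seed = 1, metric = "accuracy")
  expect_gt(xgb$best_score, knn$best_score)
})
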