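test_that("imputation preserves observed cells and completes the table", {
  inj <- small_mafld_cohort(n = 250, seed = 2)
  obs <- !inj$cohort$mask
  for (m in c("mice_tree", "knn_imputer", "missforest",
              "mean_baseline")) {
    done <- impute(inj$cohort, m, seed = 1)
    expect_false(anyNA(done$values))
    for (v in colnames(obs)) {
      expect_identical(done$values[[v]][obs[, v]],
                       inj$cohort$values[[v]][obs[, v]])
    }
    bin <- done$values[["retino"]]
    expect_true(all(bin %in% c(0, 1)))
  }
})

test_that("a complete table is returned unchanged with a warning", {
  ct <- toy_cohort(30)
  expect_warning(out <- impute(ct, "mice_ridge"), "no missing")
  expect_identical(out$values, ct$values)
})

test_that("KNN imputation with k = all records gives the observed column mean", {
  ct <- toy_cohort(25, n_cont = 2, n_bin = 0, seed = 4)
  masked <- mask_cells(ct, data.frame(row = 7, var = "v1"))
  done <- impute(masked, "knn_imputer", params = list(k = 24))
  expect_equal(done$values$v1[7],
               mean(masked$values$v1, na.rm = TRUE), tolerance = 1e-10)
})

test_that("chained ridge recovers a strong linear relationship", {
  set.seed(11)
  n <- 1000
  sch <- toy_schema(2, 0)
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.1)
  ct <- cohort_table(data.frame(v1 = x, v2 = y,
                                y = rep_len(c(0, 1), n)), sch)
  # MAR in v2 driven by v1
  hit <- order(-plogis(2 * x), seq_len(n))[seq_len(200)]
  masked <- mask_cells(ct, data.frame(row = hit, var = "v2"))
  done <- impute(masked, "mice_ridge", seed = 1)
  truth <- y[hit]
  pred <- done$values$v2[hit]
  r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  expect_gte(r2, 0.9)
})

test_that("scorecard closed forms hold", {
  inj <- small_mafld_cohort(n = 200, seed = 5)
  truth <- inj$truth
  # perfect imputation: restore the generating values
  ct <- generate_cohort(cohort_sim_config(n_records = 200, seed = 5))
  sc <- score_imputation(ct, truth, "perfect")
  expect_equal(sc$weighted_continuous, 1)
  expect_equal(sc$weighted_binary, 1)
  expect_true(all(sc$per_variable$metric == 1))

  # constant imputation at the truth mean gives R^2 = 0
  const <- ct
  for (v in unique(truth$variable)) {
    rows <- truth[truth$variable == v, ]
    if (const$schema$kind[const$schema$name == v] != "continuous") next
    const$values[match(rows$record_id, const$record_ids), v] <-
      mean(rows$true_value)
  }
  sc0 <- score_imputation(const, truth, "const")
  cont <- sc0$per_variable[sc0$per_variable$kind == "continuous", ]
  expect_true(all(abs(cont$metric) < 1e-10))
})

test_that("the weighted average follows its definition", {
  sch <- variable_schema(
    name = c("a", "b", "y"), kind = c("continuous", "continuous",
                                      "binary"),
    lower = c(-1e6, -1e6, NA), upper = c(1e6, 1e6, NA),
    positive_label = c(NA, NA, "case"),
    role = c("feature", "feature", "target"))
  n <- 10
  set.seed(1)
  truth_a <- rnorm(4); truth_b <- rnorm(8)
  vals <- data.frame(a = rnorm(n), b = rnorm(n),
                     y = rep_len(c(0, 1), n))
  vals$a[1:4] <- truth_a; vals$b[1:8] <- truth_b
  ct <- cohort_table(vals, sch)
  truth <- rbind(
    data.frame(record_id = 1:4, variable = "a", true_value = truth_a),
    data.frame(record_id = 1:8, variable = "b", true_value = truth_b))
  # engineer per-variable R^2 of 0.5 (a) and 0.8 (b): weights 0.4, 0.8
  ct$values$a[1:4] <- truth_a +
    sqrt(0.5 * var(truth_a) * 3 / 4) * c(1, -1, 1, -1)
  ct$values$b[1:8] <- truth_b +
    sqrt(0.2 * var(truth_b) * 7 / 8) * rep(c(1, -1), 4)
  sc <- score_imputation(ct, truth)
  pv <- sc$per_variable
  w <- pv$weight; m <- pv$metric
  expect_equal(sc$weighted_continuous, sum(w * m) / sum(w))
  # the worked example: weights 0.2/0.4 with metrics 0.5/0.8 average 0.7
  expect_equal((0.2 * 0.5 + 0.4 * 0.8) / 0.6, 0.7)
  # aggregate lies between the per-variable extremes
  expect_gte(sc$weighted_continuous, min(m))
  expect_lte(sc$weighted_continuous, max(m))
})

test_that("scorecards are invariant to variable order and weights equalise to a plain mean", {
  inj <- small_mafld_cohort(n = 200, seed = 6)
  done <- impute(inj$cohort, "mice_tree", seed = 2)
  sc1 <- score_imputation(done, inj$truth)
  sc2 <- score_imputation(done, inj$truth[rev(seq_len(nrow(inj$truth))), ])
  expect_equal(sc1$weighted_continuous, sc2$weighted_continuous)
  pv <- sc1$per_variable[sc1$per_variable$kind == "continuous", ]
  # equal weights would reduce the aggregate to the plain mean
  expect_equal(sum(rep(0.3, nrow(pv)) * pv$metric) / (0.3 * nrow(pv)),
               mean(pv$metric))
})

test_that("the benchmark returns one scorecard per method per seed and is deterministic", {
  ct <- generate_cohort(cohort_sim_config(n_records = 700, seed = 21))
  rates <- default_missingness_rates()
  rates[rates > 0] <- 0.04   # keep a usable complete subset
  inj <- inject_missingness(ct, missingness_config("MAR", rates = rates,
                                                   seed = 21))
  run <- function() run_benchmark(
    inj$cohort, methods = c("mice_ridge", "mice_tree", "knn_imputer"),
    seeds = 1, classifiers = "logistic_regression", folds = 3,
    min_complete = 20)
  b1 <- run()
  expect_equal(length(b1$scorecards), 4L)     # 3 methods + baseline
  expect_true(b1$winner %in% c("mice_ridge", "mice_tree", "knn_imputer"))
  b2 <- run()
  expect_equal(b1$summary, b2$summary)
})

test_that("chained equations beat mean imputation on strongly linear data", {
  set.seed(31)
  n <- 800
  sch <- toy_schema(3, 0)
  x <- rnorm(n)
  vals <- data.frame(v1 = x, v2 = 1.5 * x + rnorm(n, sd = 0.2),
                     v3 = -x + rnorm(n, sd = 0.2),
                     y = rep_len(c(0, 1), n))
  ct <- cohort_table(vals, sch)
  hit2 <- sample(n, 160); hit3 <- sample(n, 120)
  masked <- mask_cells(ct, data.frame(
    row = c(hit2, hit3), var = rep(c("v2", "v3"), c(160, 120))))
  truth <- rbind(
    data.frame(record_id = hit2, variable = "v2",
               true_value = vals$v2[hit2]),
    data.frame(record_id = hit3, variable = "v3",
               true_value = vals$v3[hit3]))
  r2_of <- function(m) {
    score_imputation(impute(masked, m, seed = 1),
                     truth)$weighted_continuous
  }
  expect_gt(r2_of("mice_ridge"), r2_of("mean_baseline"))
})
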