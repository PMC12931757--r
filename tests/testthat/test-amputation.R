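test_that("half split partitions records with near-equal sizes", {
  ct <- toy_cohort(100)
  h <- split_halves(ct, seed = 1)
  expect_equal(nrow(h$half_a$values), 50L)
  expect_equal(nrow(h$half_b$values), 50L)
  expect_setequal(c(h$half_a$record_ids, h$half_b$record_ids),
                  ct$record_ids)

  ct2 <- toy_cohort(101)
  h2 <- split_halves(ct2, seed = 2)
  expect_equal(sort(c(nrow(h2$half_a$values), nrow(h2$half_b$values))),
               c(50L, 51L))
  expect_length(intersect(h2$half_a$record_ids, h2$half_b$record_ids), 0L)
  h2b <- split_halves(ct2, seed = 2)
  expect_identical(h2$half_a$record_ids, h2b$half_a$record_ids)
})

test_that("complete-subset extraction keeps only fully observed rows", {
  ct <- toy_cohort(10, n_cont = 2)
  masked <- mask_cells(ct, data.frame(row = c(1, 3, 3), var = "v1"))
  comp <- extract_complete_subset(masked)
  expect_equal(nrow(comp$values), 8L)
  expect_false(any(comp$mask))
  expect_identical(extract_complete_subset(ct)$values, ct$values)
  all_missing <- mask_cells(ct, data.frame(row = 1:10, var = "v2"))
  expect_warning(empty <- extract_complete_subset(all_missing),
                 "empty")
  expect_equal(nrow(empty$values), 0L)
})

test_that("one missingness classifier is fitted per column with missing cells", {
  ct <- toy_cohort(200, n_cont = 4, n_bin = 1, seed = 3)
  masked <- mask_cells(ct, data.frame(
    row = c(sample(200, 40), sample(200, 30)),
    var = rep(c("v1", "v3"), c(40, 30))))
  choices <- fit_missingness_classifiers(
    masked, classifiers = c("logistic_regression", "decision_tree"),
    folds = 3, seed = 1)
  expect_setequal(names(choices), c("v1", "v3"))
  expect_true(all(vapply(choices, function(c) c$cv_f1, 1) >= 0))
  expect_true(all(vapply(choices, function(c) c$cv_f1, 1) <= 1))
  expect_equal(choices$v1$target_ratio, 40 / 200)
})

test_that("a learnable missingness mechanism is recovered with high F1", {
  set.seed(5)
  n <- 2000
  ct <- toy_cohort(n, n_cont = 3, n_bin = 0, seed = 5)
  # missing iff v1 > median, flipped with probability 0.05
  flag <- (ct$values$v1 > median(ct$values$v1)) != (runif(n) < 0.05)
  masked <- mask_cells(ct, data.frame(row = which(flag), var = "v2"))
  choices <- fit_missingness_classifiers(
    masked, classifiers = c("logistic_regression", "decision_tree"),
    folds = 3, seed = 1)
  expect_gte(choices$v2$cv_f1, 0.85)
})

test_that("amputation nulls exactly the top-probability records", {
  ct <- toy_cohort(200, n_cont = 3, n_bin = 0, seed = 7)
  train <- toy_cohort(300, n_cont = 3, n_bin = 0, seed = 8)
  masked <- mask_cells(train, data.frame(
    row = which(train$values$v1 > 0.3), var = "v2"))
  choices <- fit_missingness_classifiers(
    masked, classifiers = "logistic_regression", folds = 3, seed = 1)
  amp <- amputate(ct, choices, target_ratios = c(v2 = 0.20))
  expect_equal(sum(amp$amputated$mask[, "v2"]), 40L)     # round(0.2*200)
  # the nulled set is the top-q of a full descending probability sort
  plan <- amp$plan$v2
  expected <- ct$record_ids[order(-plan$probabilities,
                                  seq_along(plan$probabilities))][1:40]
  expect_identical(plan$amputated, expected)
  # ground truth is preserved exactly
  idx <- match(plan$amputated, ct$record_ids)
  expect_identical(plan$truth, ct$values$v2[idx])
  # zero ratio nulls nothing
  amp0 <- amputate(ct, choices, target_ratios = c(v2 = 0))
  expect_equal(sum(amp0$amputated$mask), 0L)
  expect_error(amputate(ct, choices, target_ratios = c(v2 = 1)),
               "invalid ratio")
})

test_that("amputation plans are deterministic under identical seeds", {
  inj <- small_mafld_cohort(n = 400, seed = 13)
  run_once <- function() {
    h <- split_halves(inj$cohort, seed = 2)
    comp <- extract_complete_subset(h$half_a)
    ch <- fit_missingness_classifiers(
      h$half_b, classifiers = "logistic_regression", folds = 3,
      seed = 2)
    amputate(comp, ch)
  }
  a <- run_once(); b <- run_once()
  expect_identical(lapply(a$plan, `[[`, "amputated"),
                   lapply(b$plan, `[[`, "amputated"))
})

test_that("replicated amputation preserves the MAR signature", {
  # learn a strongly age-driven mechanism, replicate it, and check the
  # amputated subset still rejects MCAR
  ct <- generate_cohort(cohort_sim_config(n_records = 1600, seed = 17))
  cfg <- missingness_config(
    "MAR", rates = c(insulin = 0.3, crp = 0.25),
    mar_drivers = list(
      insulin = list(weights = c(age = 3), intercept = 0),
      crp = list(weights = c(bmi = 3), intercept = 0)),
    seed = 17)
  inj <- inject_missingness(ct, cfg)
  h <- split_halves(inj$cohort, seed = 1)
  comp <- extract_complete_subset(h$half_a)
  ch <- fit_missingness_classifiers(
    h$half_b, classifiers = "logistic_regression", folds = 3, seed = 1)
  amp <- amputate(comp, ch)
  sub <- amp$amputated$values[c("age", "bmi", "insulin", "crp")]
  expect_true(littles_mcar_test(as.matrix(sub))$reject)
})
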