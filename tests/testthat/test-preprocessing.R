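test_that("range filtering nulls out-of-range cells and keeps boundaries", {
  sch <- variable_schema(
    name = c("alt", "y"), kind = c("continuous", "binary"),
    lower = c(1, NA), upper = c(3000, NA),
    positive_label = c(NA, "case"), role = c("feature", "target"))
  ct <- cohort_table(data.frame(alt = c(-5, 1, 3000, 150),
                                y = c(0, 1, 0, 1)), sch)
  out <- apply_range_filter(ct)
  expect_true(out$cohort$mask[1, "alt"])
  expect_false(any(out$cohort$mask[2:4, "alt"]))    # closed interval
  expect_equal(out$report$n_out_of_range[
    out$report$variable == "alt"], 1L)
  again <- apply_range_filter(out$cohort)
  expect_identical(again$cohort$values, out$cohort$values)
})

test_that("sparse features and rows are dropped under strict thresholds", {
  set.seed(2)
  n <- 100
  ct <- toy_cohort(n, n_cont = 4, n_bin = 0)
  # v1 at exactly 45%: retained; v2 at 46%: dropped
  cells <- rbind(
    data.frame(row = 1:45, var = "v1"),
    data.frame(row = 1:46, var = "v2"))
  masked <- mask_cells(ct, cells)
  out <- drop_sparse(masked, 0.45, 0.50)
  expect_true("v1" %in% out$cohort$schema$name)
  expect_false("v2" %in% out$cohort$schema$name)

  # a row missing 3 of 4 features (75% > 50%) is dropped; one missing
  # 2 of 4 (exactly 50%) is retained under the strict inequality
  masked2 <- mask_cells(ct, data.frame(
    row = c(99, 99, 99, 98, 98), var = c("v1", "v3", "v4", "v1", "v3")))
  out2 <- drop_sparse(masked2, 0.45, 0.50)
  expect_false(99 %in% out2$cohort$record_ids)
  expect_true(98 %in% out2$cohort$record_ids)

  # exact duplicates: first occurrence kept
  dup <- ct$values
  dup[50, ] <- dup[49, ]
  out3 <- drop_sparse(cohort_table(dup, ct$schema), 0.45, 0.50)
  expect_equal(nrow(out3$cohort$values), n - 1L)
  expect_true(49 %in% out3$cohort$record_ids)
})

test_that("cleaning is idempotent", {
  inj <- small_mafld_cohort(n = 300, seed = 3)
  once <- drop_sparse(inj$cohort)
  twice <- drop_sparse(once$cohort)
  expect_identical(once$cohort$values, twice$cohort$values)
})

test_that("sensitivity analysis reports SMD 0 and KS p 1 for coinciding scenarios", {
  # all per-column rates below the lowest threshold: scenarios coincide
  ct <- generate_cohort(cohort_sim_config(n_records = 400, seed = 4))
  rates <- default_missingness_rates()
  rates[rates > 0] <- 0.05
  inj <- inject_missingness(ct, missingness_config("MCAR", rates = rates,
                                                   seed = 4))
  rep <- sensitivity_analysis(inj$cohort, thresholds = c(0.30, 0.45,
                                                         0.60))
  expect_true(all(rep$smd < 0.01))
  expect_true(all(rep$ks_p == 1.00))
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("LOF flags an isolated point and none among identical points", {
  set.seed(6)
  sch <- toy_schema(2, 0)
  X <- matrix(runif(99 * 2), 99, 2)
  vals <- data.frame(v1 = c(X[, 1], 100), v2 = c(X[, 2], 100),
                     y = rep_len(c(0, 1), 100))
  ct <- cohort_table(vals, sch)
  res <- detect_outliers_lof(ct, k_neighbors = 10, threshold = 1.5)
  expect_true(100 %in% res$flagged)
  expect_equal(which.max(res$scores), 100L)

  same <- cohort_table(data.frame(v1 = rep(1, 30), v2 = rep(2, 30),
                                  y = rep_len(c(0, 1), 30)), sch)
  expect_length(detect_outliers_lof(same, k_neighbors = 5)$flagged, 0L)
  expect_error(detect_outliers_lof(same, k_neighbors = 30), "< n")
})

test_that("LOF scores are invariant to affine rescaling of a feature", {
  ct <- toy_cohort(80, n_cont = 3, n_bin = 0, seed = 7)
  s1 <- detect_outliers_lof(ct, k_neighbors = 10)$scores
  resc <- ct$values
  resc$v2 <- 1000 * resc$v2 + 55
  s2 <- detect_outliers_lof(cohort_table(resc, ct$schema),
                            k_neighbors = 10)$scores
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("undersampling equalises classes as a subset of the input", {
  set.seed(8)
  sch <- toy_schema(1, 0)
  vals <- data.frame(v1 = rnorm(300), y = rep(c(0, 1), c(180, 120)))
  ct <- cohort_table(vals, sch)
  bal <- balance_undersample(ct, seed = 1)
  expect_equal(as.integer(table(bal$values$y)), c(120L, 120L))
  expect_true(all(bal$record_ids %in% ct$record_ids))
  balanced <- cohort_table(data.frame(v1 = rnorm(20),
                                      y = rep_len(c(0, 1), 20)), sch)
  expect_identical(balance_undersample(balanced)$values,
                   balanced$values)
})

test_that("SMOTE interpolates synthetic minority records", {
  set.seed(9)
  sch <- toy_schema(2, 1)
  n0 <- 20L; n1 <- 10L
  vals <- data.frame(v1 = rnorm(n0 + n1), v2 = rnorm(n0 + n1),
                     b1 = rbinom(n0 + n1, 1, 0.5),
                     y = rep(c(0, 1), c(n0, n1)))
  ct <- cohort_table(vals, sch)
  bal <- balance_smote(ct, k_neighbors = 3, seed = 2)
  expect_equal(as.integer(table(bal$values$y)), c(20L, 20L))
  expect_true(all(ct$record_ids %in% bal$record_ids))   # superset
  # synthetic rows lie on segments between minority pairs
  syn <- bal$values[-seq_len(n0 + n1), ]
  minr <- vals[vals$y == 1, c("v1", "v2")]
  on_segment <- vapply(seq_len(nrow(syn)), function(i) {
    p <- as.numeric(syn[i, c("v1", "v2")])
    any(vapply(seq_len(nrow(minr)), function(a) {
      any(vapply(seq_len(nrow(minr)), function(b) {
        if (a == b) return(FALSE)
        A <- as.numeric(minr[a, ]); B <- as.numeric(minr[b, ])
        d <- B - A
        lam <- if (abs(d[1]) > abs(d[2])) (p[1] - A[1]) / d[1] else
          (p[2] - A[2]) / d[2]
        lam >= -1e-8 && lam <= 1 + 1e-8 &&
          max(abs(A + lam * d - p)) < 1e-8
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
  expect_true(all(syn$b1 %in% c(0, 1)))
  expect_error(balance_smote(ct, k_neighbors = 15), "exceed")
})
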