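test_that("schema invariants are enforced", {
  expect_error(variable_schema("a", "continuous", lower = 2, upper = 1,
                               role = "target"),
               "target")
  expect_error(
    variable_schema(c("a", "a", "y"), c("continuous", "continuous",
                                        "binary"),
                    role = c("feature", "feature", "target")),
    "unique")
  expect_error(
    variable_schema(c("a", "y"), c("continuous", "binary"),
                    lower = c(5, NA), upper = c(1, NA),
                    role = c("feature", "target")),
    "lower < upper")
  sch <- mafld_schema()
  expect_equal(nrow(sch), 32L)          # 31 predictors + target
  expect_equal(sum(sch$role == "target"), 1L)
  expect_equal(sum(sch$kind == "continuous"), 25L)
})

test_that("CSV round trip reproduces values, mask and ids; missing tokens and bad cells handled", {
  sch <- toy_schema(2, 1)
  path <- tempfile(fileext = ".csv")
  writeLines(c("record_id,v1,v2,b1,y",
               "r1,1.5,,1,0",
               "r2,NA,2.25,0,1",
               "r3,nan,-3,1,0",
               "r4,abc,4,0,1"), path)
  expect_warning(ct <- read_cohort_csv(path, sch, id_column = "record_id"),
                 "1 unparseable")
  expect_equal(dim(ct$values), c(4L, 4L))
  # NA / nan tokens and the unparseable cell are all missing
  expect_equal(unname(ct$mask[, "v1"]), c(FALSE, TRUE, TRUE, TRUE))
  expect_true(ct$mask[1, "v2"])         # blank cell
  expect_equal(ct$values$v2[2], 2.25)

  out <- tempfile(fileext = ".csv")
  write_cohort_csv(ct, out)
  ct2 <- read_cohort_csv(out, sch, id_column = "record_id")
  expect_equal(ct2$values, ct$values)
  expect_equal(ct2$mask, ct$mask)
  expect_equal(as.character(ct2$record_ids), as.character(ct$record_ids))
})

test_that("schema mismatch and empty input are rejected on read", {
  sch <- toy_schema(2, 0)
  path <- tempfile(fileext = ".csv")
  writeLines(c("v1,y", "1,0"), path)
  expect_error(read_cohort_csv(path, sch), "v2")
  writeLines("v1,v2,y", path)
  expect_error(read_cohort_csv(path, sch), "empty")
})

test_that("group summary handles constant and symmetric cases", {
  set.seed(4)
  n <- 200L
  sch <- toy_schema(1, 1)
  vals <- data.frame(v1 = rep(2.5, n),
                     b1 = rep(c(1, 1, 0, 0), n / 4),
                     y = rep(c(0, 1), n / 2))
  ct <- cohort_table(vals, sch)
  gs <- summarize_by_group(ct)
  expect_equal(gs$p_value[gs$variable == "v1"], 1.0)
  # 2x2 counts [[50,50],[50,50]]: independence by symmetry
  expect_equal(gs$p_value[gs$variable == "b1"], 1.0)
  expect_equal(gs$pct_0[gs$variable == "b1"], 50)
})

test_that("group summary requires a complete target and two classes", {
  ct <- toy_cohort(20)
  ct$values$y <- 0
  expect_error(summarize_by_group(cohort_table(ct$values, ct$schema)),
               "degenerate")
})

test_that("quartiles satisfy Q1 <= Q3 and class means are class-conditional", {
  inj <- small_mafld_cohort(n = 400, seed = 2)
  gs <- summarize_by_group(inj$cohort)
  cont <- gs[gs$kind == "continuous", ]
  expect_true(all(cont$q1_0 <= cont$q3_0))
  expect_true(all(cont$q1_1 <= cont$q3_1))
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))
  # strongly separated variable rejects at large n
  expect_lt(cont$p_value[cont$variable == "alt"], 0.001)
})

test_that("group-comparison p-values are uniform under identical class generators", {
  sch <- toy_schema(1, 0)
  pvals <- vapply(seq_len(250), function(r) {
    set.seed(r)
    vals <- data.frame(v1 = rnorm(60), y = rep_len(c(0, 1), 60))
    summarize_by_group(cohort_table(vals, sch))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("write_report writes CSV for frames and JSON for lists", {
  dir <- tempfile()
  paths <- write_report(list(summary = data.frame(a = 1:2, b = c("x", "y")),
                             meta = list(seed = 3, note = "ok")), dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "meta.json")))
  back <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(back$a, 1:2)
  expect_equal(jsonlite::read_json(file.path(dir, "meta.json"))$seed, 3)
})
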