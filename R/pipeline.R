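#' Pipeline configuration
#'
#' One structured configuration for the whole analysis flow. Any section
#' may be overridden; defaults run a desk-scale synthetic study.
#'
#' @param input_csv optional cohort CSV; when `NULL` a synthetic cohort
#'   is generated.
#' @param n_records,prevalence synthetic-cohort size and class-1
#'   fraction (used when `input_csv` is `NULL`).
#' @param seed global seed; every stage derives its randomness from it.
#' @param out_dir report output directory.
#' @param stages named logical/character toggles: `clean`, `diagnose`,
#'   `impute_bench`, `outliers`, `balance` (`"undersample"`, `"smote"`
#'   or `FALSE`), `model`.
#' @param missingness a [missingness_config()] for synthetic injection.
#' @param bench benchmark controls: `seeds`, `methods`, `classifiers`,
#'   `folds`, `min_complete`.
#' @param lof LOF controls: `k`, `threshold`.
#' @param model modelling controls: `classifier_ids`,
#'   `selection_methods`, `folds`, `repeat_seeds`, `train_fraction`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL, n_records = 2000L,
                            prevalence = 0.5, seed = 1L,
                            out_dir = tempfile("mafldml_run_"),
                            stages = list(),
                            missingness = NULL,
                            bench = list(), lof = list(),
                            model = list()) {
  stages <- utils::modifyList(
    list(clean = TRUE, diagnose = TRUE, impute_bench = TRUE,
         impute = TRUE, outliers = TRUE, balance = "undersample",
         model = TRUE), stages)
  bench <- utils::modifyList(
    list(seeds = seed + 0:1, methods = imputer_ids(),
         classifiers = c("logistic_regression", "decision_tree",
                         "random_forest", "extreme_gradient_boosting"),
         folds = 3L, min_complete = 100L), bench)
  lof <- utils::modifyList(list(k = 20L, threshold = 1.5), lof)
  model <- utils::modifyList(
    list(classifier_ids = c("logistic_regression",
                            "extreme_gradient_boosting"),
         selection_methods = c("none"), folds = 5L,
         repeat_seeds = seed + 0:2, train_fraction = 0.8), model)
  if (is.null(missingness)) {
    missingness <- missingness_config(seed = seed)
  }
  structure(list(input_csv = input_csv, n_records = as.integer(n_records),
                 prevalence = prevalence, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages,
                 missingness = missingness, bench = bench, lof = lof,
                 model = model),
            class = "pipeline_config")
}

# Cheap deterministic content fingerprint for the run manifest.
stage_hash <- function(ct) {
  v <- as.matrix(ct$values)
  sprintf("%dx%d-%.6f-%d", nrow(v), ncol(v),
          sum(v, na.rm = TRUE) + sum(abs(v), na.rm = TRUE) / 3,
          sum(ct$mask))
}

#' Run the full analysis pipeline
#'
#' Ingest or generate -> clean -> missingness diagnostics -> imputation
#' benchmark -> impute with the winning method -> LOF outlier removal ->
#' class balancing -> stratified split -> feature selection -> training
#' and evaluation -> importance aggregation. Every stage's report is
#' written under `config$out_dir` and a manifest records seeds and stage
#' fingerprints. Any stage error aborts with the stage name and a
#' partial manifest on disk.
#'
#' @param config a [pipeline_config()].
#' @return list(reports, manifest) invisibly-written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  reports <- list()
  finish_stage <- function(name, ct) {
    manifest$stages[[name]] <<- stage_hash(ct)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ingest / generate
  ct <- run_stage("ingest", {
    if (!is.null(config$input_csv)) {
      read_cohort_csv(config$input_csv, mafld_schema())
    } else {
      complete <- generate_cohort(cohort_sim_config(
        n_records = config$n_records, prevalence = config$prevalence,
        seed = config$seed))
      inj <- inject_missingness(complete, config$missingness)
      inj$cohort
    }
  })
  finish_stage("ingest", ct)

  if (isTRUE(config$stages$clean)) {
    ct <- run_stage("clean", {
      rf <- apply_range_filter(ct)
      ds <- drop_sparse(rf$cohort)
      reports$cleaning <- list(range_filter = rf$report,
                                sparse = ds$report)
      ds$cohort
    })
    finish_stage("clean", ct)
  }

  if (isTRUE(config$stages$diagnose)) {
    run_stage("diagnose", {
      inv <- missingness_inventory(ct)
      lt <- tryCatch(littles_mcar_test(ct), error = function(e) {
        list(error = conditionMessage(e))
      })
      reports$missingness <- list(
        inventory = inv,
        littles_test = lt[c("d2", "df", "p_value", "n_patterns")])
      utils::write.csv(inv,
                       file.path(config$out_dir, "missingness.csv"),
                       row.names = FALSE)
    })
    finish_stage("diagnose", ct)
  }

  winner <- "mice_ridge"
  if (isTRUE(config$stages$impute_bench)) {
    bench <- run_stage("impute_bench", {
      b <- run_benchmark(ct, methods = config$bench$methods,
                         seeds = config$bench$seeds,
                         classifiers = config$bench$classifiers,
                         folds = config$bench$folds,
                         min_complete = config$bench$min_complete)
      utils::write.csv(b$summary,
                       file.path(config$out_dir,
                                 "imputation_benchmark.csv"),
                       row.names = FALSE)
      b
    })
    winner <- bench$winner
    reports$imputation_benchmark <- bench$summary
    finish_stage("impute_bench", ct)
  }

  if (isTRUE(config$stages$impute) &&
      anyNA(ct$values[schema_features(ct$schema)])) {
    ct <- run_stage("impute", {
      impute(ct, winner, seed = config$seed)
    })
    finish_stage("impute", ct)
  }

  if (isTRUE(config$stages$outliers)) {
    ct <- run_stage("outliers", {
      res <- detect_outliers_lof(ct, k_neighbors = config$lof$k,
                                 threshold = config$lof$threshold)
      reports$outliers <- list(n_flagged = length(res$flagged),
                                flagged = res$flagged)
      if (length(res$flagged)) {
        cohort_subset(ct, -match(res$flagged, ct$record_ids))
      } else ct
    })
    finish_stage("outliers", ct)
  }

  if (!isFALSE(config$stages$balance)) {
    ct <- run_stage("balance", {
      if (identical(config$stages$balance, "smote")) {
        balance_smote(ct, seed = config$seed)
      } else {
        balance_undersample(ct, seed = config$seed)
      }
    })
    finish_stage("balance", ct)
  }

  if (isTRUE(config$stages$model)) {
    if (anyNA(ct$values[schema_features(ct$schema)])) {
      stop("pipeline stage 'model' failed: modelling requires a ",
           "complete table (enable the imputation stage)", call. = FALSE)
    }
    model_out <- run_stage("model", {
      sp <- split_train_test(ct, fraction = config$model$train_fraction,
                             seed = config$seed)
      grid_rows <- list(); model_reports <- list()
      for (cid in config$model$classifier_ids) {
        tuned <- tune_classifier(sp$train, cid,
                                 folds = config$model$folds,
                                 seed = config$seed)
        for (sel_m in config$model$selection_methods) {
          sel <- select_features(sp$train, sel_m, cid,
                                 params = list(
                                   classifier_params = tuned$best_params,
                                   folds = config$model$folds),
                                 seed = config$seed)
          rep_ <- evaluate_model(sp$train, sp$test, cid, sel,
                                 params = tuned$best_params,
                                 folds = config$model$folds,
                                 seeds = config$model$repeat_seeds)
          model_reports[[paste(cid, sel_m, sep = "+")]] <- rep_
          acc <- rep_$pooled[rep_$pooled$metric == "accuracy", ]
          grid_rows[[length(grid_rows) + 1L]] <- data.frame(
            classifier = cid, selection = sel_m,
            n_features = rep_$n_selected, cv_accuracy = acc$mean,
            cv_sd = acc$sd, ci_low = acc$ci_low, ci_high = acc$ci_high,
            test_accuracy = rep_$test_metrics[["accuracy"]],
            test_auc = rep_$test_metrics[["auc"]])
        }
      }
      grid <- do.call(rbind, grid_rows)
      utils::write.csv(grid, file.path(config$out_dir, "model_grid.csv"),
                       row.names = FALSE)
      imp <- tryCatch(aggregate_importance(model_reports),
                      error = function(e) NULL)
      if (!is.null(imp)) {
        utils::write.csv(imp,
                         file.path(config$out_dir,
                                   "feature_importance.csv"),
                         row.names = FALSE)
      }
      list(grid = grid, reports = model_reports, importance = imp)
    })
    reports$model_grid <- model_out$grid
    reports$model_reports <- model_out$reports
    reports$importance <- model_out$importance
    finish_stage("model", ct)
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(reports = reports, manifest = manifest,
                 cohort = ct))
}
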