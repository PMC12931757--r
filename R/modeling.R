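# Outcome modelling: stratified split, grid-search CV, feature
# selection (filter, PCA, recursive elimination, genetic-algorithm
# wrapper), CI-reported evaluation and feature-importance aggregation.

#' Stratified train/test split
#'
#' @param table a [cohort_table()] with a complete binary target.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return list(train, test); class proportions preserved within one
#'   record per class.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L) {
  y <- table$values[[schema_target(table$schema)]]
  if (any(table(factor(y, levels = c(0, 1))) < 2L)) {
    stop("stratification error: each class needs at least 2 records",
         call. = FALSE)
  }
  set.seed(seed)
  tr <- integer(0)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    tr <- c(tr, sample(idx, round(fraction * length(idx))))
  }
  tr <- sort(tr)
  list(train = cohort_subset(table, tr),
       test = cohort_subset(table, setdiff(seq_along(y), tr)))
}

#' Tune a classifier by stratified grid-search CV
#'
#' @param train a complete [cohort_table()].
#' @param classifier_id classifier id (see [default_classifier_grid()]).
#' @param grid list of parameter lists; defaults to the family grid.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return list(best_params, best_score, trace), ties broken by grid
#'   order.
#' @export
tune_classifier <- function(train, classifier_id, grid = NULL,
                            folds = 5L, seed = 1L) {
  X <- feature_matrix(train)
  y <- train$values[[schema_target(train$schema)]]
  cv_grid_search(classifier_id, X, y, grid = grid, folds = folds,
                 metric = "accuracy", seed = seed)
}

# --- feature scoring (filter method) ----------------------------------

# One-way ANOVA F statistic of a continuous feature against the class.
anova_f_score <- function(x, y) {
  groups <- split(x, y)
  k <- length(groups); n <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Mutual information (nats) between two binary variables.
binary_mutual_information <- function(x, y) {
  tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

#' Select features for a wrapped classifier
#'
#' Four strategies: `select_k_best` ranks features univariately (ANOVA F
#' for continuous, mutual information for binary) and tunes k by CV
#' accuracy of the wrapped classifier; `pca` projects standardised
#' features onto principal components and tunes the component count;
#' `rfecv` recursively eliminates the least-important feature, choosing
#' the subset size with the best CV score; `genetic_algorithm` evolves
#' binary feature masks with CV-accuracy fitness, its own hyperparameters
#' chosen from a Taguchi L9 orthogonal array. `none` selects everything.
#'
#' @param train a complete [cohort_table()].
#' @param method one of `none`, `select_k_best`, `pca`, `rfecv`,
#'   `genetic_algorithm`.
#' @param classifier_id the wrapped classifier.
#' @param params method parameters: `k_grid` / `component_grid` (tuning
#'   grids), `classifier_params`, `folds`, `ga` (a [ga_config()]).
#' @param seed integer seed.
#' @return A `selection_result`: method, selected feature names (or
#'   component projection), and the tuning trace.
#' @export
select_features <- function(train, method = c("none", "select_k_best",
                                              "pca", "rfecv",
                                              "genetic_algorithm"),
                            classifier_id = "logistic_regression",
                            params = list(), seed = 1L) {
  method <- match.arg(method)
  X <- feature_matrix(train)
  y <- train$values[[schema_target(train$schema)]]
  feats <- colnames(X)
  folds <- params$folds %||% 5L
  cpar <- params$classifier_params %||% list()
  score_subset <- function(Xs) {
    fold <- stratified_folds(y, folds, seed)
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- fit_classifier(classifier_id, Xs[tr, , drop = FALSE], y[tr],
                            cpar, seed = seed)
      prob <- predict_classifier(fit, Xs[!tr, , drop = FALSE])
      classification_metrics(y[!tr], prob)[["accuracy"]]
    }, numeric(1)))
  }
  res <- switch(method,
    none = list(selected = feats, trace = NULL),
    select_k_best = {
      kinds <- train$schema$kind[match(feats, train$schema$name)]
      scores <- vapply(seq_along(feats), function(j) {
        if (kinds[j] == "continuous") anova_f_score(X[, j], y)
        else binary_mutual_information(X[, j], y)
      }, numeric(1))
      ranked <- feats[order(-scores, feats)]
      k_grid <- params$k_grid %||%
        unique(pmin(c(5, 10, 15, 20, 25, length(feats)), length(feats)))
      if (any(k_grid > length(feats))) {
        stop("k exceeds feature count", call. = FALSE)
      }
      trace <- data.frame(k = k_grid, cv_accuracy = NA_real_)
      for (i in seq_along(k_grid)) {
        keep <- ranked[seq_len(k_grid[i])]
        trace$cv_accuracy[i] <- score_subset(X[, keep, drop = FALSE])
      }
      best_k <- trace$k[which.max(trace$cv_accuracy)]
      list(selected = ranked[seq_len(best_k)], scores = scores,
           trace = trace)
    },
    pca = {
      scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
      pc <- stats::prcomp(X, center = TRUE, scale. = scl)
      grid <- params$component_grid %||%
        unique(pmin(c(5, 10, 15, 20, 25, length(feats)), ncol(pc$x)))
      trace <- data.frame(n_components = grid, cv_accuracy = NA_real_)
      for (i in seq_along(grid)) {
        trace$cv_accuracy[i] <-
          score_subset(pc$x[, seq_len(grid[i]), drop = FALSE])
      }
      k <- trace$n_components[which.max(trace$cv_accuracy)]
      list(selected = paste0("PC", seq_len(k)), pca = pc,
           n_components = k, trace = trace)
    },
    rfecv = {
      current <- feats
      trace <- list()
      best <- list(score = -Inf, features = feats)
      while (length(current) >= 1L) {
        sc <- score_subset(X[, current, drop = FALSE])
        trace[[length(trace) + 1L]] <- data.frame(
          n_features = length(current), cv_accuracy = sc)
        if (sc > best$score) best <- list(score = sc, features = current)
        if (length(current) == 1L) break
        fit <- fit_classifier(classifier_id,
                              X[, current, drop = FALSE], y, cpar,
                              seed = seed)
        imp <- model_importance(fit, current)
        if (is.null(imp)) {
          imp <- vapply(current, function(v) {
            kind <- train$schema$kind[train$schema$name == v]
            if (kind == "continuous") anova_f_score(X[, v], y)
            else binary_mutual_information(X[, v], y)
          }, numeric(1))
        }
        current <- current[current != current[which.min(imp)]]
      }
      list(selected = best$features, trace = do.call(rbind, trace))
    },
    genetic_algorithm = {
      ga <- ga_taguchi_select(X, y, classifier_id, cpar,
                              config = params$ga %||% ga_config(),
                              folds = folds, seed = seed)
      list(selected = feats[as.logical(ga$best_mask)],
           trace = ga$trace, fitness = ga$best_fitness,
           ga_settings = ga$settings)
    }
  )
  structure(c(list(method = method, classifier_id = classifier_id), res),
            class = "selection_result")
}

#' Apply a selection result to a cohort's feature matrix
#' @param selection a `selection_result`.
#' @param table a complete [cohort_table()].
#' @return Numeric matrix in the selected feature (or component) space.
#' @export
apply_selection <- function(selection, table) {
  X <- feature_matrix(table)
  if (selection$method == "pca") {
    stats::predict(selection$pca, X)[,
      seq_len(selection$n_components), drop = FALSE]
  } else {
    X[, selection$selected, drop = FALSE]
  }
}

# --- genetic-algorithm wrapper selection ------------------------------

#' Genetic-algorithm configuration
#'
#' Defaults: tournament selection of size 3, elitism 1, uniform
#' crossover, per-bit mutation, 40 generations with early stop after 10
#' stagnant generations. The Taguchi levels span population size,
#' crossover rate and mutation rate.
#'
#' @param population_size,n_generations,crossover_rate,mutation_rate GA
#'   search controls.
#' @param tournament_size,elitism,stagnation selection pressure, elite
#'   carry-over count, and early-stop patience in generations.
#' @param taguchi_levels named list of 3 levels for each of
#'   population_size, crossover_rate, mutation_rate.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20L, n_generations = 40L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      tournament_size = 3L, elitism = 1L,
                      stagnation = 10L,
                      taguchi_levels = list(
                        population_size = c(10L, 20L, 30L),
                        crossover_rate = c(0.6, 0.8, 0.9),
                        mutation_rate = c(0.01, 0.05, 0.1))) {
  stopifnot(population_size >= 2, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(as.list(environment()), class = "ga_config")
}

#' The L9(3^3) Taguchi orthogonal array
#'
#' Nine rows covering three 3-level factors such that every factor pair
#' appears in all nine level combinations exactly once.
#' @return A 9 x 3 integer matrix of level indices.
#' @export
taguchi_l9 <- function() {
  matrix(c(1, 1, 1,
           1, 2, 2,
           1, 3, 3,
           2, 1, 2,
           2, 2, 3,
           2, 3, 1,
           3, 1, 3,
           3, 2, 1,
           3, 3, 2), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("population_size", "crossover_rate",
                                 "mutation_rate")))
}

ga_taguchi_select <- function(X, y, classifier_id, cpar, config, folds,
                              seed) {
  arr <- taguchi_l9()
  lv <- config$taguchi_levels
  trace <- list()
  best <- NULL
  for (r in seq_len(nrow(arr))) {
    cfg <- config
    cfg$population_size <- lv$population_size[arr[r, 1]]
    cfg$crossover_rate <- lv$crossover_rate[arr[r, 2]]
    cfg$mutation_rate <- lv$mutation_rate[arr[r, 3]]
    run <- ga_run(X, y, classifier_id, cpar, cfg, folds,
                  seed = seed + r)
    trace[[r]] <- data.frame(
      row = r, population_size = cfg$population_size,
      crossover_rate = cfg$crossover_rate,
      mutation_rate = cfg$mutation_rate,
      best_fitness = run$best_fitness,
      n_selected = sum(run$best_mask),
      generations = run$generations)
    if (is.null(best) || run$best_fitness > best$best_fitness) {
      best <- run
      best$settings <- cfg[c("population_size", "crossover_rate",
                             "mutation_rate")]
    }
  }
  best$trace <- do.call(rbind, trace)
  best
}

ga_run <- function(X, y, classifier_id, cpar, config, folds, seed) {
  p <- ncol(X)
  set.seed(seed)
  fold <- stratified_folds(y, folds, seed)
  cache <- new.env(hash = TRUE)
  fitness <- function(mask) {
    if (!any(mask)) return(0)
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    Xs <- X[, mask, drop = FALSE]
    acc <- mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- fit_classifier(classifier_id, Xs[tr, , drop = FALSE],
                            y[tr], cpar, seed = seed)
      prob <- predict_classifier(fit, Xs[!tr, , drop = FALSE])
      classification_metrics(y[!tr], prob)[["accuracy"]]
    }, numeric(1)))
    cache[[key]] <- acc
    acc
  }
  pop <- matrix(stats::runif(config$population_size * p) < 0.5,
                config$population_size, p)
  pop[rowSums(pop) == 0L, 1L] <- TRUE
  fit_vals <- apply(pop, 1L, fitness)
  best_i <- which.max(fit_vals)
  best <- list(mask = pop[best_i, ], fitness = fit_vals[best_i])
  stagnant <- 0L; gen <- 0L
  for (gen in seq_len(config$n_generations)) {
    newpop <- matrix(FALSE, config$population_size, p)
    # elitism
    ord <- order(-fit_vals)
    for (e in seq_len(min(config$elitism, config$population_size))) {
      newpop[e, ] <- pop[ord[e], ]
    }
    for (i in seq(config$elitism + 1L, config$population_size)) {
      pa <- tournament_pick(fit_vals, config$tournament_size)
      pb <- tournament_pick(fit_vals, config$tournament_size)
      child <- if (stats::runif(1) < config$crossover_rate) {
        take <- stats::runif(p) < 0.5
        ifelse(take, pop[pa, ], pop[pb, ])
      } else pop[pa, ]
      flip <- stats::runif(p) < config$mutation_rate
      child[flip] <- !child[flip]
      if (!any(child)) child[sample.int(p, 1L)] <- TRUE
      newpop[i, ] <- child
    }
    pop <- newpop
    fit_vals <- apply(pop, 1L, fitness)
    gi <- which.max(fit_vals)
    if (fit_vals[gi] > best$fitness + 1e-12) {
      best <- list(mask = pop[gi, ], fitness = fit_vals[gi])
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= config$stagnation) break
    }
  }
  list(best_mask = best$mask, best_fitness = best$fitness,
       generations = gen)
}

tournament_pick <- function(fit_vals, size) {
  cand <- sample.int(length(fit_vals), min(size, length(fit_vals)))
  cand[which.max(fit_vals[cand])]
}

# --- evaluation -------------------------------------------------------

#' Evaluate a classifier with repeated stratified cross-validation
#'
#' Per repeat seed, a stratified k-fold split of the training set gives
#' per-fold accuracy/precision/recall/F1 (threshold 0.5) and AUC; the
#' 95\% CI uses the t distribution with `folds - 1` degrees of freedom.
#' Held-out test metrics come from a single fit on all of the training
#' set. Feature selection must already be fitted on the training set
#' only.
#'
#' @param train,test complete [cohort_table()]s.
#' @param classifier_id classifier id.
#' @param selection a `selection_result` fitted on `train`.
#' @param params classifier hyperparameters (e.g. from
#'   [tune_classifier()]).
#' @param folds CV folds per repeat.
#' @param seeds one repeat per seed (default 10 repeats).
#' @return A `model_report`: per-fold metrics, per-repeat and pooled
#'   mean/SD/CI, test metrics, normalised feature importances.
#' @export
evaluate_model <- function(train, test, classifier_id, selection = NULL,
                           params = list(), folds = 5L, seeds = 1:10) {
  if (is.null(selection)) {
    selection <- select_features(train, "none", classifier_id)
  }
  Xtr <- apply_selection(selection, train)
  Xte <- apply_selection(selection, test)
  y <- train$values[[schema_target(train$schema)]]
  yte <- test$values[[schema_target(test$schema)]]
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  per_fold <- list()
  for (r in seq_along(seeds)) {
    fold <- stratified_folds(y, folds, seeds[r])
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      fit <- fit_classifier(classifier_id, Xtr[tr, , drop = FALSE],
                            y[tr], params, seed = seeds[r])
      prob <- predict_classifier(fit, Xtr[!tr, , drop = FALSE])
      m <- classification_metrics(y[!tr], prob)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_ = r, fold = f, t(m))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  per_repeat <- do.call(rbind, lapply(split(per_fold, per_fold$repeat_),
    function(d) {
      mns <- colMeans(d[metric_names])
      sds <- apply(d[metric_names], 2, stats::sd)
      half <- stats::qt(0.975, df = nrow(d) - 1) * sds / sqrt(nrow(d))
      data.frame(repeat_ = d$repeat_[1], metric = metric_names,
                 mean = mns, sd = sds, ci_low = mns - half,
                 ci_high = mns + half, row.names = NULL)
    }))
  pooled <- data.frame(
    metric = metric_names,
    mean = colMeans(per_fold[metric_names]),
    sd = apply(per_fold[metric_names], 2, stats::sd), row.names = NULL)
  nf <- nrow(per_fold)
  half <- stats::qt(0.975, df = nf - 1) * pooled$sd / sqrt(nf)
  pooled$ci_low <- pooled$mean - half
  pooled$ci_high <- pooled$mean + half

  final <- fit_classifier(classifier_id, Xtr, y, params,
                          seed = seeds[1])
  test_metrics <- classification_metrics(
    yte, predict_classifier(final, Xte))
  imp <- model_importance(final, colnames(Xtr))
  if (!is.null(imp)) {
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  structure(list(classifier_id = classifier_id,
                 selection_method = selection$method,
                 n_selected = length(selection$selected),
                 params = params, per_fold = per_fold,
                 per_repeat = per_repeat, pooled = pooled,
                 test_metrics = test_metrics, importance = imp,
                 folds = folds, seeds = seeds),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  acc <- x$pooled[x$pooled$metric == "accuracy", ]
  cat(sprintf(
    "<model_report> %s + %s (%d features): CV accuracy %.3f +/- %.3f [%.3f, %.3f]; test accuracy %.3f, AUC %.3f\n",
    x$classifier_id, x$selection_method, x$n_selected, acc$mean, acc$sd,
    acc$ci_low, acc$ci_high, x$test_metrics[["accuracy"]],
    x$test_metrics[["auc"]]))
  invisible(x)
}

# Normalisable per-feature importance of a fitted classifier, or NULL
# when the family exposes none (e.g. k-NN, RBF-SVM).
model_importance <- function(fit, feature_names) {
  if (!is.null(fit$constant)) return(NULL)
  m <- fit$model
  imp <- switch(fit$id,
    logistic_regression = {
      # per-SD effect size so scales are comparable across features
      co <- m$coef[-1]
      co[is.na(co)] <- 0
      stats::setNames(abs(co) * m$sds, feature_names)
    },
    decision_tree = rpart_importance(m, feature_names),
    random_forest = m$variable.importance,
    extra_trees = m$variable.importance,
    adaptive_boosting = {
      if (is.null(m$stumps)) return(NULL)
      total <- stats::setNames(numeric(length(feature_names)),
                               feature_names)
      for (i in seq_along(m$stumps)) {
        si <- rpart_importance(m$stumps[[i]], feature_names)
        total <- total + m$alphas[i] * si
      }
      total
    },
    gradient_boosting = xgb_importance_vec(m, feature_names),
    extreme_gradient_boosting = xgb_importance_vec(m, feature_names),
    light_gradient_boosting = xgb_importance_vec(m, feature_names),
    NULL
  )
  if (is.null(imp)) return(NULL)
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  out[names(imp)[names(imp) %in% feature_names]] <-
    imp[names(imp) %in% feature_names]
  out
}

rpart_importance <- function(m, feature_names) {
  vi <- m$variable.importance
  if (is.null(vi)) vi <- stats::setNames(numeric(0), character(0))
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  out[names(vi)[names(vi) %in% feature_names]] <-
    vi[names(vi) %in% feature_names]
  out
}

xgb_importance_vec <- function(m, feature_names) {
  tab <- tryCatch(xgboost::xgb.importance(model = m),
                  error = function(e) NULL)
  if (is.null(tab)) return(NULL)
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  out[tab$Feature[tab$Feature %in% feature_names]] <-
    tab$Gain[tab$Feature %in% feature_names]
  out
}

#' Mean normalised feature importance across the best models
#'
#' Importances are taken from each report (already normalised to sum to
#' one), averaged across the top `k` reports by pooled CV accuracy, and
#' ranked; ties are broken by feature name. Reports without importances
#' (e.g. k-NN) or in a different feature space are excluded with a log
#' attribute.
#'
#' @param reports list of `model_report`s.
#' @param k number of top models to average over.
#' @param top_n number of leading features to flag in the ranking.
#' @return Data frame (feature, mean_importance, rank, top) plus
#'   per-model columns; excluded models in `attr(, "excluded")`.
#' @export
aggregate_importance <- function(reports, k = 3L, top_n = 10L) {
  has_imp <- vapply(reports, function(r) !is.null(r$importance),
                    logical(1))
  excluded <- vapply(reports[!has_imp], `[[`, character(1),
                     "classifier_id")
  reports <- reports[has_imp]
  if (!length(reports)) stop("no reports expose importances",
                             call. = FALSE)
  spaces <- lapply(reports, function(r) sort(names(r$importance)))
  ref <- spaces[[which.max(vapply(reports, function(r) {
    r$pooled$mean[r$pooled$metric == "accuracy"]
  }, numeric(1)))]]
  same <- vapply(spaces, identical, logical(1), ref)
  excluded <- c(excluded, vapply(reports[!same], `[[`, character(1),
                                 "classifier_id"))
  reports <- reports[same]
  acc <- vapply(reports, function(r) {
    r$pooled$mean[r$pooled$metric == "accuracy"]
  }, numeric(1))
  top <- reports[order(-acc)][seq_len(min(k, length(reports)))]
  M <- vapply(top, function(r) r$importance[ref], numeric(length(ref)))
  M <- matrix(M, nrow = length(ref),
              dimnames = list(ref, vapply(top, `[[`, character(1),
                                          "classifier_id")))
  mean_imp <- rowMeans(M)
  ord <- order(-mean_imp, ref)
  out <- data.frame(feature = ref[ord], mean_importance = mean_imp[ord],
                    rank = seq_along(ref),
                    top = seq_along(ref) <= top_n,
                    M[ord, , drop = FALSE], row.names = NULL,
                    check.names = FALSE)
  attr(out, "excluded") <- excluded
  out
}
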