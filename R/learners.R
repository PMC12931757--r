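# Unified fit/predict layer over the classifier and regressor families
# used by the missingness classifiers, the chained-equations imputers and
# the outcome models. Every backend is seeded and single-threaded so that
# whole-pipeline runs are reproducible.

CLASSIFIER_IDS <- c("logistic_regression", "k_nearest_neighbors",
                    "support_vector_machine", "decision_tree",
                    "random_forest", "extra_trees", "adaptive_boosting",
                    "extreme_gradient_boosting")

MODEL_IDS <- c("logistic_regression", "k_nearest_neighbors",
               "support_vector_machine", "decision_tree", "extra_trees",
               "gradient_boosting", "extreme_gradient_boosting",
               "light_gradient_boosting")

REGRESSOR_IDS <- c("ridge", "svm", "tree", "random_forest", "extra_trees",
                   "adaboost", "gbdt")

#' Default hyperparameter grids for the classifier families
#'
#' Compact literature-standard grids; every entry is overridable by
#' passing an explicit grid to the tuning functions. A grid is a list of
#' named parameter assignments.
#'
#' @param id classifier identifier.
#' @return List of parameter lists.
#' @export
default_classifier_grid <- function(id) {
  switch(id,
    logistic_regression = list(list()),
    k_nearest_neighbors = lapply(c(3, 5, 11), function(k) list(k = k)),
    support_vector_machine = lapply(c(0.1, 1, 10), function(C)
      list(cost = C)),
    decision_tree = lapply(c(3, 5, 10), function(d) list(maxdepth = d)),
    random_forest = lapply(c(100, 300), function(nt)
      list(num_trees = nt)),
    extra_trees = lapply(c(100, 300), function(nt) list(num_trees = nt)),
    adaptive_boosting = lapply(c(50, 100), function(m)
      list(n_rounds = m, maxdepth = 1)),
    gradient_boosting = lapply(c(3, 5), function(d)
      list(max_depth = d, nrounds = 100, eta = 0.1)),
    extreme_gradient_boosting = lapply(c(3, 5), function(d)
      list(max_depth = d, nrounds = 100, eta = 0.1)),
    light_gradient_boosting = lapply(c(15, 31), function(l)
      list(max_leaves = l, nrounds = 100, eta = 0.1)),
    stop("unknown classifier id: ", id, call. = FALSE)
  )
}

#' Fit a binary classifier
#'
#' @param id one of the classifier identifiers (see
#'   [default_classifier_grid()] for the families).
#' @param X numeric feature matrix (complete).
#' @param y 0/1 outcome vector.
#' @param params named parameter list for the family.
#' @param seed integer seed for stochastic learners.
#' @return A `mafld_clf` object for [predict_classifier()].
#' @export
fit_classifier <- function(id, X, y, params = list(), seed = 1L) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    # Degenerate training outcome: constant-probability model.
    return(structure(list(id = id, constant = mean(y)),
                     class = "mafld_clf"))
  }
  set.seed(seed)
  model <- switch(id,
    logistic_regression = {
      co <- suppressWarnings(stats::glm.fit(
        cbind(1, X), y, family = stats::binomial()))$coefficients
      list(coef = co, sds = apply(X, 2, stats::sd))
    },
    k_nearest_neighbors = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
      list(train = scale(X, ctr, scl), y = factor(y, levels = c(0, 1)),
           ctr = ctr, scl = scl, k = params$k %||% 5)
    },
    support_vector_machine = suppressWarnings(e1071::svm(
      X, factor(y, levels = c(0, 1)), kernel = "radial",
      cost = params$cost %||% 1, gamma = params$gamma %||% (1 / ncol(X)),
      probability = TRUE, scale = apply(X, 2, stats::sd) > 0)),
    decision_tree = {
      df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth %||% 5,
                     cp = params$cp %||% 0.001, xval = 0))
    },
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees %||% 300,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(X)))),
      importance = "impurity", num.threads = 1, seed = seed),
    extra_trees = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees %||% 300, splitrule = "extratrees",
      replace = FALSE, sample.fraction = 1,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(X)))),
      importance = "impurity", num.threads = 1, seed = seed),
    adaptive_boosting = adaboost_samme_fit(
      X, y, n_rounds = params$n_rounds %||% 50,
      maxdepth = params$maxdepth %||% 1),
    gradient_boosting = xgb_fit(X, y, params, seed,
                                objective = "binary:logistic",
                                flavor = "exact"),
    extreme_gradient_boosting = xgb_fit(X, y, params, seed,
                                        objective = "binary:logistic",
                                        flavor = "xgb"),
    light_gradient_boosting = xgb_fit(X, y, params, seed,
                                      objective = "binary:logistic",
                                      flavor = "hist_lossguide"),
    stop("unknown classifier id: ", id, call. = FALSE)
  )
  structure(list(id = id, model = model, p = ncol(X),
                 colnames = colnames(X)), class = "mafld_clf")
}

#' Predict class-1 probabilities from a fitted classifier
#'
#' @param fit a `mafld_clf`.
#' @param X numeric feature matrix.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_classifier <- function(fit, X) {
  X <- as_feature_matrix(X)
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(X)))
  m <- fit$model
  switch(fit$id,
    logistic_regression = {
      co <- m$coef
      eta <- drop(cbind(1, X) %*% ifelse(is.na(co), 0, co))
      stats::plogis(eta)
    },
    k_nearest_neighbors = {
      k <- min(m$k, nrow(m$train))
      pr <- class::knn(m$train, scale(X, m$ctr, m$scl), m$y, k = k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    support_vector_machine = {
      pred <- stats::predict(m, X, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    decision_tree = stats::predict(m, data.frame(X), type = "prob")[, "1"],
    random_forest = stats::predict(m, X,
                                   num.threads = 1)$predictions[, "1"],
    extra_trees = stats::predict(m, X,
                                 num.threads = 1)$predictions[, "1"],
    adaptive_boosting = adaboost_samme_predict(m, X),
    gradient_boosting = xgb_predict(m, X),
    extreme_gradient_boosting = xgb_predict(m, X),
    light_gradient_boosting = xgb_predict(m, X),
    stop("unknown classifier id: ", fit$id, call. = FALSE)
  )
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  X
}

xgb_fit <- function(X, y, params, seed, objective, flavor) {
  base <- list(objective = objective, eta = params$eta %||% 0.1,
               nthread = 1, verbosity = 0, seed = seed)
  if (flavor == "exact") {
    # classic depth-wise gradient boosting without shrinkage penalties
    base$tree_method <- "exact"
    base$max_depth <- params$max_depth %||% 3
    base$lambda <- params$lambda %||% 0
    base$subsample <- params$subsample %||% 1
  } else if (flavor == "hist_lossguide") {
    # leaf-wise growth with histogram binning
    base$tree_method <- "hist"
    base$grow_policy <- "lossguide"
    base$max_depth <- 0
    base$max_leaves <- params$max_leaves %||% 31
  } else {
    base$max_depth <- params$max_depth %||% 6
  }
  dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = base, data = dtr,
                     nrounds = params$nrounds %||% 100)
}

xgb_predict <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
}

# --- AdaBoost (SAMME, decision stumps by default) ---------------------

adaboost_samme_fit <- function(X, y, n_rounds = 50, maxdepth = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  df <- data.frame(X, .y = yf)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          xval = 0))
    pred <- as.numeric(as.character(stats::predict(fit, df,
                                                   type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-10) {
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (!length(stumps)) {
    return(list(constant = mean(y)))
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_samme_predict <- function(model, X) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  df <- data.frame(X)
  score <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(stats::predict(model$stumps[[m]], df,
                                                   type = "class")))
    score <- score + model$alphas[m] * (2 * pred - 1)
  }
  margin <- score / sum(model$alphas)
  (margin + 1) / 2
}

# --- Regressors (chained-equations estimator families) ----------------

#' Fit a regressor of one of the imputation estimator families
#'
#' @param id one of `ridge`, `svm`, `tree`, `random_forest`,
#'   `extra_trees`, `adaboost`, `gbdt`.
#' @param X numeric feature matrix (complete).
#' @param y numeric outcome.
#' @param params named parameter list.
#' @param seed integer seed.
#' @return A `mafld_reg` object for [predict_regressor()].
#' @export
fit_regressor <- function(id, X, y, params = list(), seed = 1L) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (stats::sd(y) == 0 || nrow(X) < 3L) {
    return(structure(list(id = id, constant = mean(y)),
                     class = "mafld_reg"))
  }
  set.seed(seed)
  model <- switch(id,
    ridge = {
      # glmnet requires >= 2 columns; pad with a zero column if needed
      pad <- ncol(X) < 2L
      Xr <- if (pad) cbind(X, .pad = 0) else X
      list(fit = glmnet::glmnet(Xr, y, alpha = 0,
                                lambda = params$lambda %||% 1e-2),
           pad = pad)
    },
    svm = suppressWarnings(e1071::svm(
      X, y, kernel = "radial", cost = params$cost %||% 1,
      scale = apply(X, 2, stats::sd) > 0)),
    tree = {
      df <- data.frame(X, .y = y)
      rpart::rpart(.y ~ ., df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth %||% 5, cp = 0.001,
                     xval = 0))
    },
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = params$num_trees %||% 100,
      num.threads = 1, seed = seed),
    extra_trees = ranger::ranger(
      x = X, y = y, num.trees = params$num_trees %||% 100,
      splitrule = "extratrees", replace = FALSE, sample.fraction = 1,
      num.threads = 1, seed = seed),
    adaboost = adaboost_r2_fit(X, y,
                               n_rounds = params$n_rounds %||% 50,
                               maxdepth = params$maxdepth %||% 3),
    gbdt = xgb_fit(X, y, params, seed, objective = "reg:squarederror",
                   flavor = "xgb"),
    stop("unknown regressor id: ", id, call. = FALSE)
  )
  structure(list(id = id, model = model), class = "mafld_reg")
}

#' Predict from a fitted regressor
#' @param fit a `mafld_reg`.
#' @param X numeric feature matrix.
#' @return Numeric predictions.
#' @export
predict_regressor <- function(fit, X) {
  X <- as_feature_matrix(X)
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(X)))
  m <- fit$model
  switch(fit$id,
    ridge = {
      Xr <- if (m$pad) cbind(X, .pad = 0) else X
      drop(stats::predict(m$fit, Xr))
    },
    svm = drop(stats::predict(m, X)),
    tree = drop(stats::predict(m, data.frame(X))),
    random_forest = stats::predict(m, X, num.threads = 1)$predictions,
    extra_trees = stats::predict(m, X, num.threads = 1)$predictions,
    adaboost = adaboost_r2_predict(m, X),
    gbdt = xgb_predict(m, X),
    stop("unknown regressor id: ", fit$id, call. = FALSE)
  )
}

# AdaBoost.R2 (Drucker) with regression-tree base learners and linear
# loss; prediction is the weighted median over rounds.
adaboost_r2_fit <- function(X, y, n_rounds = 50, maxdepth = 3) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(X, .y = y)
  trees <- list(); betas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w * n, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.001, xval = 0))
    pred <- stats::predict(fit, df)
    err <- abs(pred - y)
    D <- max(err)
    if (D <= 1e-12) {
      trees[[length(trees) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    L <- err / D
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    trees[[length(trees) + 1L]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  if (!length(trees)) return(list(constant = stats::median(y)))
  list(trees = trees, log_inv_beta = log(1 / betas))
}

adaboost_r2_predict <- function(model, X) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  df <- data.frame(X)
  P <- vapply(model$trees, function(tr) stats::predict(tr, df),
              numeric(nrow(df)))
  P <- matrix(P, nrow = nrow(df))
  wts <- model$log_inv_beta
  apply(P, 1L, function(row) weighted_median(row, wts))
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}

# --- CV utilities -----------------------------------------------------

#' Stratified fold assignment
#'
#' @param y 0/1 outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold index per record.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

classification_metrics <- function(y, prob, threshold = 0.5) {
  pred <- as.numeric(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc <- if (length(unique(y)) == 2L) {
    as.numeric(pROC::auc(y, prob, direction = "<", quiet = TRUE,
                         levels = c(0, 1)))
  } else NA_real_
  c(accuracy = (tp + tn) / length(y), precision = precision,
    recall = recall, f1 = f1, auc = auc)
}

#' Grid-search a classifier by stratified cross-validation
#'
#' Exhaustive evaluation of a parameter grid by mean CV score; ties are
#' broken by grid order. Single-class folds are skipped with a log
#' attribute; grid cells where the learner fails are recorded as failed
#' and excluded.
#'
#' @param id classifier id.
#' @param X complete numeric feature matrix.
#' @param y 0/1 outcome.
#' @param grid list of parameter lists (default
#'   [default_classifier_grid()]).
#' @param folds number of CV folds.
#' @param metric `"accuracy"` or `"f1"`.
#' @param seed integer seed (controls the fold split and learners).
#' @return list(best_params, best_score, trace) where trace has one row
#'   per grid cell per fold.
#' @export
cv_grid_search <- function(id, X, y, grid = NULL, folds = 5L,
                           metric = c("accuracy", "f1"), seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(grid)) grid <- default_classifier_grid(id)
  if (!length(grid)) stop("empty grid", call. = FALSE)
  fold <- stratified_folds(y, folds, seed)
  trace <- list()
  means <- numeric(length(grid))
  for (g in seq_along(grid)) {
    scores <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L || !any(te)) {
        trace[[length(trace) + 1L]] <- data.frame(
          cell = g, fold = f, score = NA_real_, failed = FALSE)
        next
      }
      ok <- tryCatch({
        fit <- fit_classifier(id, X[tr, , drop = FALSE], y[tr],
                              grid[[g]], seed = seed)
        prob <- predict_classifier(fit, X[te, , drop = FALSE])
        scores[f] <- classification_metrics(y[te], prob)[[metric]]
        TRUE
      }, error = function(e) FALSE)
      trace[[length(trace) + 1L]] <- data.frame(
        cell = g, fold = f, score = scores[f], failed = !ok)
    }
    means[g] <- mean(scores, na.rm = TRUE)
  }
  means[!is.finite(means)] <- -Inf
  best <- which.max(means)
  list(best_params = grid[[best]], best_score = means[best],
       best_cell = best,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}
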