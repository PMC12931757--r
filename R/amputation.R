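# Learned-MAR amputation: learn each column's missingness mechanism on
# one half of the data, then replicate it onto a fully observed subset of
# the other half by probability-ranked amputation at the observed rate.

#' Randomly split a cohort into two halves
#'
#' @param table a [cohort_table()].
#' @param seed integer seed.
#' @return list(half_a, half_b); sizes differ by at most one record.
#' @export
split_halves <- function(table, seed = 1L) {
  n <- n_records(table)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  a <- sort(idx[seq_len(ceiling(n / 2))])
  b <- sort(idx[-seq_len(ceiling(n / 2))])
  list(half_a = cohort_subset(table, a), half_b = cohort_subset(table, b))
}

#' Extract the fully observed subset of a cohort
#'
#' @param table a [cohort_table()].
#' @return A [cohort_table()] with an all-false mask; a warning is issued
#'   when the result is empty.
#' @export
extract_complete_subset <- function(table) {
  keep <- rowSums(table$mask) == 0L
  if (!any(keep)) {
    warning("no complete rows: complete subset is empty", call. = FALSE)
  }
  cohort_subset(table, which(keep))
}

#' Fit per-column missingness classifiers
#'
#' For every column with at least one missing and one observed cell, the
#' missingness indicator (missing = 1) is modelled from all other feature
#' columns; candidate classifiers are grid-searched by stratified CV and
#' the winner per column is chosen by mean F1 (ties broken by classifier
#' order). Missing entries in predictor columns are placeholder-filled
#' with the column median (continuous) or mode (binary) for training.
#'
#' @param half_b a [cohort_table()] (typically one half of the data).
#' @param classifiers candidate classifier ids (default: the eight
#'   missingness-model families).
#' @param grids optional named list of per-classifier grids.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return list of per-column choices: column, classifier_id, best_params,
#'   cv_f1, fit (refit on all of half_b), target_ratio; columns entirely
#'   missing or entirely observed are skipped with a `skipped` attribute.
#' @export
fit_missingness_classifiers <- function(half_b,
                                        classifiers = CLASSIFIER_IDS,
                                        grids = NULL, folds = 3L,
                                        seed = 1L) {
  if (n_records(half_b) == 0L) stop("half_b is empty", call. = FALSE)
  tgt <- schema_target(half_b$schema)
  feats <- schema_features(half_b$schema)
  Xfill <- placeholder_fill(half_b)
  choices <- list(); skipped <- character(0)
  n <- n_records(half_b)
  for (col in feats) {
    y <- as.numeric(half_b$mask[, col])
    if (sum(y) == 0L || sum(y) == n) {
      if (sum(y) == n) skipped <- c(skipped, col)
      next
    }
    X <- as.matrix(Xfill[setdiff(feats, col)])
    best <- NULL
    for (id in classifiers) {
      cv <- cv_grid_search(id, X, y, grid = grids[[id]], folds = folds,
                          metric = "f1", seed = seed)
      if (is.null(best) || cv$best_score > best$cv_f1) {
        best <- list(column = col, classifier_id = id,
                     best_params = cv$best_params, cv_f1 = cv$best_score)
      }
    }
    best$fit <- fit_classifier(best$classifier_id, X, y,
                               best$best_params, seed = seed)
    best$predictors <- setdiff(feats, col)
    best$target_ratio <- mean(y)
    choices[[col]] <- best
  }
  attr(choices, "skipped") <- skipped
  choices
}

# Median/mode placeholder completion of the feature columns.
placeholder_fill <- function(table) {
  vals <- table$values
  for (v in schema_features(table$schema)) {
    x <- vals[[v]]
    if (!anyNA(x)) next
    kind <- table$schema$kind[table$schema$name == v]
    fill <- if (kind == "continuous") {
      stats::median(x, na.rm = TRUE)
    } else {
      obs <- x[!is.na(x)]
      if (length(obs)) as.numeric(names(which.max(table(obs)))) else 0
    }
    if (!is.finite(fill)) fill <- 0
    x[is.na(x)] <- fill
    vals[[v]] <- x
  }
  vals
}

#' Amputate a complete subset by predicted missingness probability
#'
#' For each column with a fitted missingness classifier, probabilities are
#' predicted from the pre-amputation (complete) values of the other
#' columns, and exactly `round(ratio * n)` cells are set missing — the
#' records with the highest predicted probability, ties broken by record
#' order. All columns' null sets are computed first and applied jointly.
#'
#' @param complete_subset a complete [cohort_table()].
#' @param choices output of [fit_missingness_classifiers()].
#' @param target_ratios optional named override of per-column ratios;
#'   defaults to each choice's observed `target_ratio`.
#' @return list(plan, amputated) where `plan` is the amputation plan
#'   (per-column ratio, probabilities, amputated record ids, ground
#'   truth) and `amputated` the masked [cohort_table()].
#' @export
amputate <- function(complete_subset, choices, target_ratios = NULL) {
  n <- n_records(complete_subset)
  if (n == 0L) stop("complete subset is empty", call. = FALSE)
  if (anyNA(complete_subset$values)) {
    stop("subset must be fully observed before amputation", call. = FALSE)
  }
  feats <- schema_features(complete_subset$schema)
  values <- complete_subset$values
  mask <- complete_subset$mask
  plan <- list()
  for (col in names(choices)) {
    ch <- choices[[col]]
    ratio <- if (!is.null(target_ratios) && col %in% names(target_ratios)) {
      target_ratios[[col]]
    } else ch$target_ratio
    if (ratio >= 1) stop("invalid ratio >= 1 for column '", col, "'",
                         call. = FALSE)
    X <- as.matrix(complete_subset$values[ch$predictors])
    prob <- predict_classifier(ch$fit, X)
    k <- round(ratio * n)
    hit <- if (k > 0) order(-prob, seq_len(n))[seq_len(k)] else integer(0)
    plan[[col]] <- list(
      column = col, classifier_id = ch$classifier_id,
      target_ratio = ratio, probabilities = prob,
      amputated = complete_subset$record_ids[hit],
      truth = complete_subset$values[hit, col]
    )
  }
  # apply jointly after all predictions are made
  for (col in names(plan)) {
    hit <- match(plan[[col]]$amputated, complete_subset$record_ids)
    if (length(hit)) {
      values[hit, col] <- NA_real_
      mask[hit, col] <- TRUE
    }
  }
  amputated <- cohort_table(values, complete_subset$schema,
                            record_ids = complete_subset$record_ids,
                            mask = mask)
  structure(list(plan = plan, amputated = amputated),
            class = "amputation_result")
}

# Flatten an amputation plan into the (record_id, variable, true_value)
# ground-truth layout used by the imputation scorer.
plan_truth <- function(plan) {
  rows <- lapply(plan, function(p) {
    if (!length(p$amputated)) return(NULL)
    data.frame(record_id = p$amputated, variable = p$column,
               true_value = p$truth)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(record_id = integer(0), variable = character(0),
                      true_value = numeric(0))
  }
  rownames(out) <- NULL
  out
}
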