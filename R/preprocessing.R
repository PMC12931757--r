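#' Null out-of-range cells
#'
#' Continuous cells outside their schema acceptable range (closed
#' interval: boundary values are retained) become missing; per-variable
#' counts are logged in the cleaning report fragment.
#'
#' @param table a [cohort_table()].
#' @return list(cohort, report) where report counts nulled cells per
#'   variable.
#' @export
apply_range_filter <- function(table) {
  sch <- table$schema
  vals <- table$values
  mask <- table$mask
  counts <- integer(0)
  for (v in schema_continuous(sch)) {
    lo <- sch$lower[sch$name == v]; hi <- sch$upper[sch$name == v]
    if (is.na(lo) && is.na(hi)) next
    x <- vals[[v]]
    bad <- !is.na(x) & ((!is.na(lo) & x < lo) | (!is.na(hi) & x > hi))
    counts[v] <- sum(bad)
    if (any(bad)) {
      x[bad] <- NA_real_
      vals[[v]] <- x
      mask[bad, v] <- TRUE
    }
  }
  report <- data.frame(variable = names(counts),
                       n_out_of_range = unname(counts))
  list(cohort = cohort_table(vals, sch, record_ids = table$record_ids,
                             mask = mask),
       report = report)
}

#' Drop sparse features, sparse rows, and duplicate rows
#'
#' Features with missing fraction strictly greater than
#' `feature_threshold` are removed first; then rows with missing fraction
#' (over the surviving features) strictly greater than `row_threshold`;
#' then exact-duplicate rows (first occurrence kept).
#'
#' @param table a [cohort_table()].
#' @param feature_threshold,row_threshold fractions in `(0, 1)`.
#' @return list(cohort, report) with the dropped features (and their
#'   missing fractions), dropped row ids, and resulting dimensions.
#' @export
drop_sparse <- function(table, feature_threshold = 0.45,
                        row_threshold = 0.50) {
  stopifnot(feature_threshold > 0, feature_threshold < 1,
            row_threshold > 0, row_threshold < 1)
  feats <- schema_features(table$schema)
  ffrac <- colMeans(table$mask[, feats, drop = FALSE])
  drop_feats <- names(ffrac)[ffrac > feature_threshold]
  ct <- if (length(drop_feats)) cohort_drop_vars(table, drop_feats) else
    table
  feats2 <- schema_features(ct$schema)
  if (!length(feats2)) stop("all features dropped", call. = FALSE)
  rfrac <- rowMeans(ct$mask[, feats2, drop = FALSE])
  drop_rows <- which(rfrac > row_threshold)
  dropped_row_ids <- ct$record_ids[drop_rows]
  if (length(drop_rows)) ct <- cohort_subset(ct, -drop_rows)
  dup <- duplicated(ct$values)
  dup_ids <- ct$record_ids[dup]
  if (any(dup)) ct <- cohort_subset(ct, which(!dup))
  report <- list(
    dropped_features = data.frame(variable = drop_feats,
                                  missing_fraction = unname(
                                    ffrac[drop_feats])),
    dropped_row_ids = dropped_row_ids,
    n_sparse_rows = length(drop_rows),
    duplicate_row_ids = dup_ids,
    dims = dim(ct$values)
  )
  list(cohort = ct, report = report)
}

#' Cleaning-threshold sensitivity analysis
#'
#' Runs the sparse-feature/row cleaning under each threshold scenario and
#' compares every scenario pair variable-by-variable with the
#' standardised mean difference and the two-sample Kolmogorov-Smirnov
#' test over the surviving cohorts.
#'
#' @param table a [cohort_table()].
#' @param thresholds numeric vector of feature thresholds (the row
#'   threshold is held at its default).
#' @return Data frame (scenario_a, scenario_b, variable, smd, ks_p).
#' @export
sensitivity_analysis <- function(table, thresholds = c(0.30, 0.45, 0.60)) {
  stopifnot(length(thresholds) >= 2L)
  cohorts <- list()
  for (th in thresholds) {
    ct <- tryCatch(drop_sparse(table, feature_threshold = th)$cohort,
                   error = function(e) NULL)
    if (is.null(ct) || n_records(ct) < 2L) {
      message("scenario ", th, " skipped (fewer than 2 records)")
      next
    }
    cohorts[[as.character(th)]] <- ct
  }
  pairs <- utils::combn(names(cohorts), 2L, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- cohorts[[pr[1]]]; b <- cohorts[[pr[2]]]
    shared <- intersect(schema_continuous(a$schema),
                        schema_continuous(b$schema))
    for (v in shared) {
      xa <- a$values[[v]][!is.na(a$values[[v]])]
      xb <- b$values[[v]][!is.na(b$values[[v]])]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_a = pr[1], scenario_b = pr[2], variable = v,
        smd = smd(xa, xb),
        ks_p = suppressWarnings(stats::ks.test(xa, xb)$p.value))
    }
  }
  do.call(rbind, rows)
}

#' Standardised mean difference
#' @param x,y numeric samples.
#' @return `|mean(x) - mean(y)| / sqrt((var(x) + var(y)) / 2)`; 0 when
#'   both variances vanish and the means agree.
#' @export
smd <- function(x, y) {
  pooled <- sqrt((stats::var(x) + stats::var(y)) / 2)
  d <- abs(mean(x) - mean(y))
  if (pooled == 0) return(if (d == 0) 0 else Inf)
  d / pooled
}

#' Local outlier factor screening
#'
#' Classic k-nearest-neighbour LOF on the standardised continuous
#' features of a complete table (run after imputation). Records are
#' flagged by score threshold, or by top fraction when `flag_fraction`
#' is given.
#'
#' @param table a complete [cohort_table()].
#' @param k_neighbors neighbourhood size (must be `< n`).
#' @param threshold LOF score above which a record is flagged.
#' @param flag_fraction optional fraction of records to flag instead of
#'   the threshold.
#' @return list(scores, flagged) with flagged record ids.
#' @export
detect_outliers_lof <- function(table, k_neighbors = 20, threshold = 1.5,
                                flag_fraction = NULL) {
  X <- as.matrix(table$values[schema_continuous(table$schema)])
  if (anyNA(X)) stop("LOF requires a complete table", call. = FALSE)
  n <- nrow(X)
  if (k_neighbors >= n) stop("k_neighbors must be < n", call. = FALSE)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Z <- scale(X, colMeans(X), scl)
  scores <- lof_scores(Z, k_neighbors)
  flagged <- if (!is.null(flag_fraction)) {
    k <- round(flag_fraction * n)
    if (k > 0) order(-scores, seq_len(n))[seq_len(k)] else integer(0)
  } else which(scores > threshold)
  list(scores = scores, flagged = table$record_ids[flagged])
}

# LOF on a numeric matrix: density ratio of each point's k-neighbourhood
# to its neighbours' neighbourhoods (reachability-distance definition).
lof_scores <- function(Z, k) {
  n <- nrow(Z)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  knn_idx <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) D[i, knn_idx[i, k]], numeric(1))
  lrd <- vapply(seq_len(n), function(i) {
    nb <- knn_idx[i, ]
    reach <- pmax(kdist[nb], D[i, nb])
    m <- mean(reach)
    if (m == 0) Inf else 1 / m
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    nb <- knn_idx[i, ]
    if (!is.finite(lrd[i])) return(1)
    r <- mean(lrd[nb]) / lrd[i]
    if (!is.finite(r)) 1 else r
  }, numeric(1))
}

#' Balance classes by random undersampling
#'
#' The majority class is randomly downsampled to the minority count; the
#' minority class is untouched.
#'
#' @param table a [cohort_table()] with a complete binary target.
#' @param seed integer seed.
#' @return A balanced [cohort_table()] (a subset of the input records).
#' @export
balance_undersample <- function(table, seed = 1L) {
  y <- table$values[[schema_target(table$schema)]]
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("degenerate class: a class is empty",
                             call. = FALSE)
  if (counts[1] == counts[2]) return(table)
  set.seed(seed)
  maj <- as.numeric(names(which.max(counts)))
  keep_maj <- sample(which(y == maj), min(counts))
  keep <- sort(c(which(y != maj), keep_maj))
  cohort_subset(table, keep)
}

#' Balance classes by SMOTE oversampling
#'
#' Synthetic minority records are generated by convex interpolation
#' between a minority record and one of its k nearest minority
#' neighbours (Euclidean distance on standardised features) until the
#' classes are equal. Binary features of a synthetic record take the
#' value of the nearest endpoint of the interpolation.
#'
#' @param table a complete [cohort_table()].
#' @param k_neighbors neighbourhood size; must be `<` the minority count.
#' @param seed integer seed.
#' @return A balanced [cohort_table()] (a superset of the input records).
#' @export
balance_smote <- function(table, k_neighbors = 5, seed = 1L) {
  tgt <- schema_target(table$schema)
  y <- table$values[[tgt]]
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("degenerate class: a class is empty",
                             call. = FALSE)
  if (counts[1] == counts[2]) return(table)
  minority <- as.numeric(names(which.min(counts)))
  min_idx <- which(y == minority)
  if (length(min_idx) <= k_neighbors) {
    stop("minority count must exceed k_neighbors", call. = FALSE)
  }
  feats <- schema_features(table$schema)
  X <- as.matrix(table$values[feats])
  if (anyNA(X)) stop("SMOTE requires a complete table", call. = FALSE)
  Xm <- X[min_idx, , drop = FALSE]
  scl <- apply(Xm, 2, stats::sd); scl[scl == 0] <- 1
  D <- as.matrix(stats::dist(scale(Xm, colMeans(Xm), scl)))
  diag(D) <- Inf
  n_new <- as.integer(max(counts) - min(counts))
  set.seed(seed)
  base <- sample(seq_along(min_idx), n_new, replace = TRUE)
  binf <- schema_binary_features(table$schema)
  new_rows <- matrix(NA_real_, n_new, length(feats),
                     dimnames = list(NULL, feats))
  for (i in seq_len(n_new)) {
    a <- base[i]
    nb <- order(D[a, ])[seq_len(k_neighbors)]
    b <- nb[sample.int(k_neighbors, 1L)]
    lam <- stats::runif(1)
    row <- Xm[a, ] + lam * (Xm[b, ] - Xm[a, ])
    row[binf] <- if (lam < 0.5) Xm[a, binf] else Xm[b, binf]
    new_rows[i, ] <- row
  }
  new_df <- as.data.frame(new_rows)
  new_df[[tgt]] <- minority
  vals <- rbind(cbind(table$values[feats], table$values[tgt]),
                new_df[c(feats, tgt)])
  ids <- c(table$record_ids,
           paste0("smote_", seq_len(n_new)))
  cohort_table(vals, table$schema, record_ids = ids)
}
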