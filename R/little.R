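#' Distinct missingness patterns of a mask
#'
#' @param mask logical records-by-variables matrix, `TRUE` = missing.
#' @return Data frame (pattern id, observed-variable count, record count),
#'   sorted by count descending, with the observed-set indicator in
#'   `attr(, "observed")` and row assignment in `attr(, "assignment")`.
#' @export
extract_patterns <- function(mask) {
  mask <- as.matrix(mask)
  if (!nrow(mask)) stop("empty mask", call. = FALSE)
  key <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  uk <- unique(key)
  counts <- as.integer(table(factor(key, levels = uk)))
  ord <- order(counts, decreasing = TRUE)
  uk <- uk[ord]; counts <- counts[ord]
  observed <- t(vapply(uk, function(k) {
    !as.logical(as.integer(strsplit(k, "")[[1]]))
  }, logical(ncol(mask))))
  colnames(observed) <- colnames(mask)
  out <- data.frame(pattern = seq_along(uk),
                    n_observed_vars = rowSums(observed),
                    count = counts)
  attr(out, "observed") <- observed
  attr(out, "assignment") <- match(key, uk)
  out
}

#' EM estimation of mean and covariance under ignorable missingness
#'
#' Maximum-likelihood estimates of the mean vector and covariance matrix
#' of an incomplete multivariate normal sample, by
#' expectation-maximisation over the missingness patterns. The
#' observed-data log-likelihood is non-decreasing across iterations;
#' convergence is declared when its change falls below `tol`.
#'
#' @param table a [cohort_table()] or numeric matrix with `NA`s.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate in its `condition` data.
#' @param ridge small diagonal inflation applied when a covariance block
#'   becomes numerically singular.
#' @return list(mean, cov, loglik, loglik_trace, n_iter, converged).
#' @export
em_mean_cov <- function(table, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  Y <- if (inherits(table, "cohort")) {
    as.matrix(table$values[schema_features(table$schema)])
  } else as.matrix(table)
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  if (any(colSums(!is.na(Y)) < 2L)) {
    stop("every variable must be observed at least twice", call. = FALSE)
  }
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]; n <- nrow(Y)

  pat <- extract_patterns(is.na(Y))
  obs_sets <- attr(pat, "observed")
  assign_ <- attr(pat, "assignment")

  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (j in seq_len(nrow(pat))) {
      rows <- which(assign_ == j)
      O <- which(obs_sets[j, ]); M <- which(!obs_sets[j, ])
      Xo <- Y[rows, O, drop = FALSE]
      So <- Sigma[O, O, drop = FALSE]
      Soi <- solve_psd(So, ridge)
      cent <- sweep(Xo, 2L, mu[O])
      ll <- ll - 0.5 * (length(rows) *
        (length(O) * log(2 * pi) + logdet_psd(So, ridge)) +
        sum((cent %*% Soi) * cent))
      if (length(M)) {
        B <- Sigma[M, O, drop = FALSE] %*% Soi
        Xm <- sweep(cent %*% t(B), 2L, mu[M], FUN = "+")
        Cc <- Sigma[M, M, drop = FALSE] -
          B %*% Sigma[O, M, drop = FALSE]
        Xfull <- matrix(0, length(rows), p)
        Xfull[, O] <- Xo; Xfull[, M] <- Xm
        S1 <- S1 + colSums(Xfull)
        S2 <- S2 + crossprod(Xfull)
        S2[M, M] <- S2[M, M] + length(rows) * Cc
      } else {
        S1 <- S1 + colSums(Xo)
        S2 <- S2 + crossprod(Xo)
      }
    }
    mu <- S1 / n
    Sigma <- S2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  names(mu) <- colnames(Y)
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))
  res <- list(mean = mu, cov = Sigma, loglik = ll_trace[length(ll_trace)],
              loglik_trace = ll_trace, n_iter = length(ll_trace),
              converged = converged)
  if (!converged) {
    cond <- simpleError(
      sprintf("EM did not converge within %d iterations", max_iter))
    cond$last_iterate <- res
    stop(cond)
  }
  res
}

solve_psd <- function(S, ridge = 1e-8) {
  tryCatch(solve(S), error = function(e) {
    solve(S + diag(ridge * max(diag(S), 1), nrow(S)))
  })
}

logdet_psd <- function(S, ridge = 1e-8) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) {
    d <- determinant(S + diag(ridge * max(diag(S), 1), nrow(S)),
                     logarithm = TRUE)
  }
  as.numeric(d$modulus)
}

#' Little's test of the MCAR hypothesis
#'
#' Compares each missingness pattern's observed-variable means against the
#' EM maximum-likelihood grand mean, pooled by the EM covariance, giving a
#' chi-square statistic `d2` with `sum_j p_j - p` degrees of freedom.
#' Rejection argues against missing-completely-at-random. Binary variables
#' enter as 0/1 numerics (a documented approximation). Every pattern
#' contributes, whatever its size: the pooled EM covariance keeps each
#' restricted block invertible, so no pattern merging is required (and
#' with many incomplete columns most patterns hold a single record).
#'
#' @param table a [cohort_table()] or numeric matrix with `NA`s.
#' @param alpha significance level used for the `reject` flag.
#' @param tol,max_iter EM controls, see [em_mean_cov()].
#' @return list(d2, df, p_value, reject, n_patterns, em_mean, em_cov).
#' @export
littles_mcar_test <- function(table, alpha = 0.05, tol = 1e-6,
                              max_iter = 500L) {
  Y <- if (inherits(table, "cohort")) {
    as.matrix(table$values[schema_features(table$schema)])
  } else as.matrix(table)
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  p <- ncol(Y)
  pat <- extract_patterns(is.na(Y))
  if (nrow(pat) < 2L) {
    stop("test undefined: data contain a single missingness pattern",
         call. = FALSE)
  }
  em <- em_mean_cov(Y, tol = tol, max_iter = max_iter)
  mu <- em$mean; Sigma <- em$cov

  obs_sets <- attr(pat, "observed")
  assign_ <- attr(pat, "assignment")
  groups <- lapply(seq_len(nrow(pat)), function(j) {
    list(rows = which(assign_ == j), obs = obs_sets[j, ])
  })
  d2 <- 0; df <- 0L
  for (g in groups) {
    O <- which(g$obs)
    if (!length(O)) next
    ybar <- colMeans(Y[g$rows, O, drop = FALSE])
    SO <- Sigma[O, O, drop = FALSE]
    SOi <- tryCatch(solve(SO), error = function(e) {
      stop("singular restricted covariance for a pattern observing: ",
           paste(colnames(Y)[O], collapse = ", "), call. = FALSE)
    })
    diffv <- ybar - mu[O]
    d2 <- d2 + length(g$rows) * drop(t(diffv) %*% SOi %*% diffv)
    df <- df + length(O)
  }
  df <- df - p
  p_value <- stats::pchisq(d2, df = df, lower.tail = FALSE)
  list(d2 = d2, df = df, p_value = p_value, reject = p_value < alpha,
       n_patterns = length(groups), em_mean = mu, em_cov = Sigma)
}

#' Per-column missingness inventory
#'
#' @param table a [cohort_table()].
#' @return Data frame (variable, n_missing, pct_missing), sorted by
#'   percentage descending.
#' @export
missingness_inventory <- function(table) {
  m <- colSums(table$mask)
  out <- data.frame(variable = colnames(table$mask), n_missing = m,
                    pct_missing = 100 * m / nrow(table$mask))
  rownames(out) <- NULL
  out[order(-out$pct_missing, out$variable), ]
}
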