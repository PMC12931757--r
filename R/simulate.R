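#' Configuration for the synthetic cohort generator
#'
#' @param n_records number of records to generate.
#' @param prevalence fraction of records in class 1 (MAFLD); the realised
#'   class counts are exact (`round(prevalence * n_records)`).
#' @param targets calibration targets as returned by
#'   [mafld_calibration_targets()]; individual entries may be edited.
#' @param copula_correlation symmetric positive-definite latent correlation
#'   matrix over the feature variables (unit diagonal). Defaults to
#'   [default_copula_correlation()].
#' @param schema variable schema; defaults to [mafld_schema()].
#' @param seed integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_records = 3654, prevalence = 0.5,
                              targets = mafld_calibration_targets(),
                              copula_correlation = NULL,
                              schema = mafld_schema(), seed = 1L) {
  stopifnot(n_records >= 1, prevalence > 0, prevalence < 1)
  feats <- schema_features(schema)
  if (is.null(copula_correlation)) {
    copula_correlation <- default_copula_correlation(feats)
  }
  R <- copula_correlation
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, nrow(R))))) {
    stop("copula correlation must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("copula correlation must be positive definite", call. = FALSE)
  }
  bad <- targets$continuous$q1 >= targets$continuous$q3
  if (any(bad)) {
    stop("calibration targets need q1 < q3: ",
         paste(unique(targets$continuous$name[bad]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 targets = targets, copula_correlation = R, schema = schema,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Default latent correlation over cohort features
#'
#' Moderate positive dependence among anthropometrics (weight, BMI, waist,
#' hip: 0.6), between the two aminotransferases (ALT/AST: 0.5), and among
#' the lipid panel (0.3); zero elsewhere. Overridable per analysis.
#'
#' @param feature_names feature variable names the matrix must cover.
#' @return Correlation matrix with dimnames.
#' @export
default_copula_correlation <- function(feature_names) {
  p <- length(feature_names)
  R <- diag(p)
  dimnames(R) <- list(feature_names, feature_names)
  set_block <- function(R, vars, rho) {
    vars <- intersect(vars, feature_names)
    for (a in vars) for (b in vars) if (a != b) R[a, b] <- rho
    R
  }
  R <- set_block(R, c("weight", "bmi", "waist", "hip"), 0.6)
  R <- set_block(R, c("alt", "ast"), 0.5)
  R <- set_block(R, c("chl", "hdl", "ldl", "tg"), 0.3)
  R
}

#' Generate a complete synthetic cohort
#'
#' Class labels are assigned at the exact configured prevalence. Each
#' continuous feature is drawn from a class-conditional shifted log-normal
#' solved to match its configured mean/Q1/Q3; binary features are drawn at
#' class-conditional rates. Cross-variable dependence is imposed through a
#' Gaussian copula, so the marginal calibration is preserved exactly.
#' Continuous values are clipped to the schema's acceptable ranges.
#'
#' @param config a [cohort_sim_config()].
#' @return A complete [cohort_table()] (no missing cells).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  schema <- config$schema
  feats <- schema_features(schema)
  tgt <- schema_target(schema)
  n <- config$n_records
  set.seed(config$seed)

  n1 <- round(config$prevalence * n)
  y <- sample(c(rep(1, n1), rep(0, n - n1)))

  # Pre-solve class-conditional marginals once.
  marginals <- solved_marginals(config$targets, schema)

  L <- chol(config$copula_correlation[feats, feats])
  Z <- matrix(stats::rnorm(n * length(feats)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- feats

  values <- as.data.frame(matrix(NA_real_, n, length(feats),
                                 dimnames = list(NULL, feats)))
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    if (!length(rows)) next
    for (v in feats) {
      kind <- schema$kind[schema$name == v]
      if (kind == "continuous") {
        par <- marginals$continuous[[v]][[as.character(cls)]]
        x <- shifted_lognormal_quantile(par, U[rows, v])
        lo <- schema$lower[schema$name == v]
        hi <- schema$upper[schema$name == v]
        if (!is.na(lo)) x <- pmax(x, lo)
        if (!is.na(hi)) x <- pmin(x, hi)
        values[rows, v] <- x
      } else {
        rate <- marginals$binary[[v]][[as.character(cls)]]
        values[rows, v] <- as.numeric(U[rows, v] < rate)
      }
    }
  }
  values[[tgt]] <- y
  cohort_table(values, schema)
}

solved_marginals <- function(targets, schema) {
  cont <- list()
  for (v in unique(targets$continuous$name)) {
    if (!v %in% schema$name) next
    cont[[v]] <- list()
    for (cls in c(0L, 1L)) {
      row <- targets$continuous[targets$continuous$name == v &
                                targets$continuous$class == cls, ]
      if (!nrow(row)) {
        stop("calibration target missing for '", v, "' class ", cls,
             call. = FALSE)
      }
      par <- solve_shifted_lognormal(row$mean, row$q1, row$q3)
      if (par$fallback) {
        message("calibration fallback (mean+Q3 only) for '", v,
                "' class ", cls)
      }
      cont[[v]][[as.character(cls)]] <- par
    }
  }
  bin <- list()
  for (v in unique(targets$binary$name)) {
    if (!v %in% schema$name) next
    bin[[v]] <- list()
    for (cls in c(0L, 1L)) {
      row <- targets$binary[targets$binary$name == v &
                            targets$binary$class == cls, ]
      bin[[v]][[as.character(cls)]] <- row$rate
    }
  }
  list(continuous = cont, binary = bin)
}

#' Configuration for missingness injection
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rates named per-column missingness fractions in `[0, 1)`;
#'   defaults to [default_missingness_rates()]. Columns listed in
#'   `always_complete` must have (or are forced to) rate 0.
#' @param always_complete variables never amputated; defaults to
#'   [always_complete_vars()].
#' @param mar_drivers for MAR: a named list mapping each target column to
#'   `list(weights = c(driver = slope, ...), intercept = 0)`. Drivers must
#'   be always-complete variables; slopes act on standardised driver
#'   values. Defaults to a slope of 1 on age and 0.5 on BMI for every
#'   column with a positive rate.
#' @param seed integer seed.
#' @return A `missingness_config` list.
#' @export
missingness_config <- function(mechanism = c("MAR", "MCAR"), rates = NULL,
                               always_complete = always_complete_vars(),
                               mar_drivers = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (is.null(rates)) rates <- default_missingness_rates()
  rates[intersect(names(rates), always_complete)] <- 0
  if (any(rates >= 1) || any(rates < 0)) {
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  }
  if (mechanism == "MAR") {
    cols <- names(rates)[rates > 0]
    if (is.null(mar_drivers)) {
      mar_drivers <- stats::setNames(rep(list(
        list(weights = c(age = 1, bmi = 0.5), intercept = 0)
      ), length(cols)), cols)
    }
    for (col in names(mar_drivers)) {
      drv <- names(mar_drivers[[col]]$weights)
      bad <- setdiff(drv, always_complete)
      if (length(bad)) {
        stop("MAR driver for '", col, "' references non-always-observed ",
             "column(s): ", paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(mechanism = mechanism, rates = rates,
                 always_complete = always_complete,
                 mar_drivers = mar_drivers, seed = as.integer(seed)),
            class = "missingness_config")
}

#' Default per-column missingness rates
#'
#' A clinic-export-like profile: specialised assays (insulin, HOMA, CRP,
#' vitamin D) missing in roughly a third of records, routine chemistry in
#' well under a tenth, and the six always-complete variables at zero.
#'
#' @return Named numeric vector of fractions.
#' @export
default_missingness_rates <- function() {
  c(age = 0, height = 0, weight = 0, dbp = 0, bmi = 0, sex = 0,
    insulin = 0.38, homa = 0.40, crp = 0.32, vitd = 0.30, hpp2 = 0.25,
    hip = 0.24, waist = 0.22, alkp = 0.18, ddm = 0.15, ua = 0.12,
    ast = 0.10, retino = 0.10, hdl = 0.09, ldl = 0.09, alt = 0.08,
    plt = 0.08, chl = 0.07, tg = 0.07, hba1c = 0.06, fbs = 0.05,
    cr = 0.05, smoking = 0.05, htn = 0.04, cad = 0.03, cva = 0.03)
}

#' Inject missingness into a complete cohort
#'
#' Under MCAR every eligible cell is independently set missing at its
#' column rate. Under MAR each record's missingness probability follows a
#' logistic model on standardised always-observed drivers, and exactly
#' `round(rate * n)` cells per column are masked by probability-weighted
#' sampling without replacement. The target column and always-complete
#' columns are never touched. Ground truth of every masked cell is
#' returned for downstream scoring.
#'
#' @param table a complete [cohort_table()].
#' @param config a [missingness_config()].
#' @return list with `cohort` (masked table) and `truth` (data frame:
#'   record_id, variable, true_value).
#' @export
inject_missingness <- function(table, config) {
  stopifnot(inherits(table, "cohort"), inherits(config, "missingness_config"))
  if (anyNA(table$values)) {
    stop("inject_missingness requires a complete table", call. = FALSE)
  }
  set.seed(config$seed)
  n <- n_records(table)
  tgt <- schema_target(table$schema)
  cols <- intersect(names(config$rates)[config$rates > 0],
                    setdiff(table$schema$name,
                            c(config$always_complete, tgt)))
  values <- table$values
  mask <- table$mask
  truth <- list()
  for (col in cols) {
    rate <- config$rates[[col]]
    if (config$mechanism == "MCAR") {
      hit <- which(stats::runif(n) < rate)
    } else {
      drv <- config$mar_drivers[[col]]
      if (is.null(drv)) next
      eta <- rep(drv$intercept %||% 0, n)
      for (d in names(drv$weights)) {
        x <- table$values[[d]]
        s <- stats::sd(x)
        z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
        eta <- eta + drv$weights[[d]] * z
      }
      p <- stats::plogis(eta)
      k <- round(rate * n)
      hit <- if (k > 0) sample.int(n, k, prob = p) else integer(0)
    }
    if (length(hit)) {
      truth[[col]] <- data.frame(record_id = table$record_ids[hit],
                                 variable = col,
                                 true_value = values[hit, col])
      values[hit, col] <- NA_real_
      mask[hit, col] <- TRUE
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(record_id = integer(0), variable = character(0),
               true_value = numeric(0))
  rownames(truth) <- NULL
  list(cohort = cohort_table(values, table$schema,
                             record_ids = table$record_ids, mask = mask),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
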