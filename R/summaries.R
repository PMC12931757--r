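#' Class-conditional descriptive summary with group-comparison tests
#'
#' For each continuous variable: per-class mean, Q1 and Q3 (type-7
#' quartiles), a Shapiro-Wilk normality p-value (pooled, capped at 5000
#' observations as the test requires), and a Kruskal-Wallis p-value for
#' the class comparison. For each binary feature: per-class count and
#' percentage of the positive label and a chi-square p-value (no
#' continuity correction; degenerate margins yield p = 1).
#'
#' @param table a [cohort_table()] whose target column is complete.
#' @return A `group_summary` data frame, one row per feature.
#' @export
summarize_by_group <- function(table) {
  stopifnot(inherits(table, "cohort"))
  tgt <- schema_target(table$schema)
  y <- table$values[[tgt]]
  if (anyNA(y)) stop("target column must be complete", call. = FALSE)
  if (length(unique(y)) < 2L || min(table(y)) == 0L) {
    stop("degenerate group: a target class has zero records", call. = FALSE)
  }
  rows <- lapply(schema_features(table$schema), function(v) {
    kind <- table$schema$kind[table$schema$name == v]
    x <- table$values[[v]]
    if (kind == "continuous") {
      stat <- lapply(c(0, 1), function(cls) {
        xi <- x[y == cls & !is.na(x)]
        c(mean = mean(xi),
          q1 = unname(stats::quantile(xi, 0.25, type = 7)),
          q3 = unname(stats::quantile(xi, 0.75, type = 7)))
      })
      xo <- x[!is.na(x)]
      norm_p <- if (length(unique(xo)) < 3L) NA_real_ else {
        xs <- if (length(xo) > 5000) sample(xo, 5000) else xo
        tryCatch(stats::shapiro.test(xs)$p.value, error = function(e) NA_real_)
      }
      comp_p <- if (length(unique(xo)) == 1L) 1.0 else {
        stats::kruskal.test(x, factor(y))$p.value
      }
      data.frame(variable = v, kind = kind,
                 mean_0 = stat[[1]][["mean"]], q1_0 = stat[[1]][["q1"]],
                 q3_0 = stat[[1]][["q3"]],
                 mean_1 = stat[[2]][["mean"]], q1_1 = stat[[2]][["q1"]],
                 q3_1 = stat[[2]][["q3"]],
                 count_0 = NA_real_, pct_0 = NA_real_,
                 count_1 = NA_real_, pct_1 = NA_real_,
                 normality_p = norm_p, p_value = comp_p)
    } else {
      n0 <- sum(x[y == 0] == 1, na.rm = TRUE)
      n1 <- sum(x[y == 1] == 1, na.rm = TRUE)
      d0 <- sum(y == 0 & !is.na(x)); d1 <- sum(y == 1 & !is.na(x))
      obs <- !is.na(x)
      tab <- table(factor(x[obs], levels = c(0, 1)),
                   factor(y[obs], levels = c(0, 1)))
      comp_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1.0
        else suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(variable = v, kind = kind,
                 mean_0 = NA_real_, q1_0 = NA_real_, q3_0 = NA_real_,
                 mean_1 = NA_real_, q1_1 = NA_real_, q3_1 = NA_real_,
                 count_0 = n0, pct_0 = 100 * n0 / max(d0, 1),
                 count_1 = n1, pct_1 = 100 * n1 / max(d1, 1),
                 normality_p = NA_real_, p_value = comp_p)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}
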