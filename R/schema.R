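#' Variable schema for a MAFLD/T2DM cohort
#'
#' A schema declares, for every variable, its name, kind (continuous or
#' binary), measurement units, acceptable physiologic range (continuous
#' only), positive label (binary only) and role (feature or target).
#' Exactly one variable must be a binary target.
#'
#' @param name character vector of unique variable names.
#' @param kind `"continuous"` or `"binary"`, per variable.
#' @param units free-text units, per variable (`""` allowed).
#' @param lower,upper acceptable range bounds for continuous variables
#'   (`NA` for binary).
#' @param positive_label value meaning "condition present" for binary
#'   variables (`NA` for continuous).
#' @param role `"feature"` or `"target"`, per variable.
#' @return A `variable_schema` data frame with one row per variable.
#' @export
variable_schema <- function(name, kind, units = "", lower = NA_real_,
                            upper = NA_real_, positive_label = NA_character_,
                            role = "feature") {
  sch <- data.frame(
    name = as.character(name),
    kind = as.character(kind),
    units = rep_len(as.character(units), length(name)),
    lower = rep_len(as.numeric(lower), length(name)),
    upper = rep_len(as.numeric(upper), length(name)),
    positive_label = rep_len(as.character(positive_label), length(name)),
    role = rep_len(as.character(role), length(name)),
    stringsAsFactors = FALSE
  )
  validate_schema(sch)
  class(sch) <- c("variable_schema", "data.frame")
  sch
}

validate_schema <- function(sch) {
  if (anyDuplicated(sch$name)) {
    stop("schema variable names must be unique", call. = FALSE)
  }
  if (!all(sch$kind %in% c("continuous", "binary"))) {
    stop("variable kind must be 'continuous' or 'binary'", call. = FALSE)
  }
  if (!all(sch$role %in% c("feature", "target"))) {
    stop("variable role must be 'feature' or 'target'", call. = FALSE)
  }
  tgt <- which(sch$role == "target")
  if (length(tgt) != 1L) {
    stop("schema must declare exactly one target variable", call. = FALSE)
  }
  if (sch$kind[tgt] != "binary") {
    stop("the target variable must be binary", call. = FALSE)
  }
  cont <- sch$kind == "continuous"
  bad <- cont & !(is.na(sch$lower) | is.na(sch$upper)) & sch$lower >= sch$upper
  if (any(bad)) {
    stop("continuous acceptable range must have lower < upper: ",
         paste(sch$name[bad], collapse = ", "), call. = FALSE)
  }
  invisible(sch)
}

#' Default 31-variable T2DM cohort schema
#'
#' Twenty-five continuous laboratory/anthropometric variables and six binary
#' history variables, plus a binary MAFLD target. The acceptable ranges are
#' broad physiologic-plausibility bounds used by the range filter; they are
#' a package convention, configurable per analysis.
#'
#' @return A `variable_schema`.
#' @export
mafld_schema <- function() {
  cont <- data.frame(
    name  = c("age", "alkp", "alt", "ast", "bmi", "chl", "cr", "crp", "dbp",
              "ddm", "fbs", "hba1c", "hdl", "height", "hip", "homa", "hpp2",
              "insulin", "ldl", "plt", "tg", "ua", "vitd", "waist", "weight"),
    units = c("years", "U/L", "U/L", "U/L", "kg/m2", "mg/dL", "mg/dL",
              "mg/L", "mmHg", "years", "mg/dL", "%", "mg/dL", "cm", "cm",
              "", "mg/dL", "uIU/mL", "mg/dL", "10^3 cells/uL", "mg/dL",
              "mg/dL", "ng/mL", "cm", "kg"),
    lower = c(20, 10, 1, 1, 10, 50, 0.2, 0, 30, 0, 40, 3, 10, 120, 50, 0,
              40, 0.1, 10, 10, 20, 1, 1, 40, 30),
    upper = c(110, 3000, 3000, 3000, 80, 600, 15, 300, 150, 60, 800, 20,
              150, 210, 200, 50, 900, 300, 400, 1000, 2000, 15, 150, 200,
              250),
    stringsAsFactors = FALSE
  )
  bin <- data.frame(
    name = c("sex", "cad", "cva", "htn", "retino", "smoking"),
    positive_label = c("female", "present", "present", "present", "present",
                       "present"),
    stringsAsFactors = FALSE
  )
  variable_schema(
    name = c(cont$name, bin$name, "mafld"),
    kind = c(rep("continuous", nrow(cont)), rep("binary", nrow(bin) + 1L)),
    units = c(cont$units, rep("", nrow(bin) + 1L)),
    lower = c(cont$lower, rep(NA_real_, nrow(bin) + 1L)),
    upper = c(cont$upper, rep(NA_real_, nrow(bin) + 1L)),
    positive_label = c(rep(NA_character_, nrow(cont)), bin$positive_label,
                       "mafld"),
    role = c(rep("feature", nrow(cont) + nrow(bin)), "target")
  )
}

schema_target <- function(schema) schema$name[schema$role == "target"]
schema_features <- function(schema) schema$name[schema$role == "feature"]
schema_continuous <- function(schema) {
  schema$name[schema$kind == "continuous"]
}
schema_binary_features <- function(schema) {
  schema$name[schema$kind == "binary" & schema$role == "feature"]
}

#' Variables that are always fully observed in the emulated cohort
#' @return Character vector of variable names.
#' @export
always_complete_vars <- function() {
  c("sex", "age", "height", "weight", "dbp", "bmi")
}

#' Construct a cohort table
#'
#' A cohort table couples a records-by-variables numeric grid with an
#' explicit missingness mask (`TRUE` = missing) and the variable schema.
#' Non-missing binary cells must be 0/1.
#'
#' @param values data frame of numeric columns, one per schema variable.
#' @param schema a `variable_schema` covering every column of `values`.
#' @param record_ids stable record identifiers (default: row numbers).
#' @param mask optional logical matrix; defaults to `is.na(values)`.
#' @return A `cohort` object.
#' @export
cohort_table <- function(values, schema, record_ids = NULL, mask = NULL) {
  validate_schema(schema)
  miss <- setdiff(schema$name, names(values))
  if (length(miss)) {
    stop("schema variables absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  values <- values[schema$name]
  values[] <- lapply(values, as.numeric)
  if (is.null(mask)) {
    mask <- as.matrix(is.na(values))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
  }
  if (!identical(dim(mask), dim(as.matrix(values)))) {
    stop("mask and values are not congruent in shape", call. = FALSE)
  }
  colnames(mask) <- names(values)
  for (b in schema$name[schema$kind == "binary"]) {
    obs <- values[[b]][!mask[, b]]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("non-missing binary cells must be 0/1 in variable '", b, "'",
           call. = FALSE)
    }
  }
  if (is.null(record_ids)) record_ids <- seq_len(nrow(values))
  structure(
    list(values = values, mask = mask, schema = schema,
         record_ids = record_ids),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n_miss <- sum(x$mask)
  cat(sprintf(
    "<cohort> %d records x %d variables (%s target), %d missing cells (%.1f%%)\n",
    nrow(x$values), ncol(x$values), schema_target(x$schema), n_miss,
    100 * n_miss / length(x$mask)
  ))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$values)

n_records <- function(ct) nrow(ct$values)

# Row subset preserving mask/schema/ids congruence.
cohort_subset <- function(ct, idx) {
  cohort_table(ct$values[idx, , drop = FALSE], ct$schema,
               record_ids = ct$record_ids[idx],
               mask = ct$mask[idx, , drop = FALSE])
}

# Column-drop counterpart; target is always retained.
cohort_drop_vars <- function(ct, drop) {
  keep <- setdiff(ct$schema$name, setdiff(drop, schema_target(ct$schema)))
  sch <- ct$schema[ct$schema$name %in% keep, , drop = FALSE]
  cohort_table(ct$values[keep], sch, record_ids = ct$record_ids,
               mask = ct$mask[, keep, drop = FALSE])
}

# Complete numeric matrix of feature columns (errors if any NA present).
feature_matrix <- function(ct, complete = TRUE) {
  X <- as.matrix(ct$values[schema_features(ct$schema)])
  if (complete && anyNA(X)) {
    stop("feature matrix contains missing values", call. = FALSE)
  }
  X
}
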