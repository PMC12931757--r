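#' Read a cohort CSV against a schema
#'
#' Binds every schema variable to a header column. Empty cells and the
#' accepted missing tokens (`""`, `"NA"`, `"NaN"`, case-insensitive)
#' become missing; unparseable cells also become missing and are counted
#' in a warning.
#'
#' @param path CSV file (RFC-4180, header row, UTF-8).
#' @param schema a `variable_schema`.
#' @param id_column optional name of a record-id column.
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, schema, id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path,
                            call. = FALSE)
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols)) {
    stop("schema mismatch: column(s) absent from header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if (!is.null(id_column) && id_column %in% names(raw)) {
    raw[[id_column]]
  } else seq_len(nrow(raw))

  tokens <- c("", "na", "nan")
  n_bad <- 0L
  values <- as.data.frame(lapply(schema$name, function(v) {
    cell <- trimws(raw[[v]])
    out <- rep(NA_real_, length(cell))
    is_token <- tolower(cell) %in% tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_token & is.na(num)
    n_bad <<- n_bad + sum(bad)
    out[!is_token & !bad] <- num[!is_token & !bad]
    out
  }))
  names(values) <- schema$name
  if (n_bad > 0L) {
    warning(n_bad, " unparseable cell(s) treated as missing", call. = FALSE)
  }
  cohort_table(values, schema, record_ids = ids)
}

#' Write a cohort to CSV
#'
#' Missing cells are written as empty fields; `read_cohort_csv()` of the
#' result reproduces values, mask and schema exactly.
#'
#' @param table a [cohort_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  out <- cbind(record_id = table$record_ids, table$values)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write report tables as CSV and JSON artifacts
#'
#' One file per report, deterministic column order. Data frames are
#' written as CSV, other structures as JSON.
#'
#' @param reports named list of data frames or lists.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(reports)) {
    obj <- reports[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
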