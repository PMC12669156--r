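#' Construct a validated cohort table
#'
#' Binds a predictor data.frame to its schema and a binary outcome vector
#' (1 = stent occlusion within one year). Every value is checked against
#' the schema: categorical labels must be known levels, bounded variables
#' must lie inside their physical range, binaries must be 0/1, and no
#' outcome may be missing.
#'
#' @param data data.frame with one column per schema variable.
#' @param outcome integer/logical vector of 0/1 outcomes, length `nrow(data)`.
#' @param schema a `cohort_schema` (default [default_schema()]).
#' @return an object of class `cohort_table` with elements `data`,
#'   `outcome`, `schema`.
#' @export
cohort_table <- function(data, outcome, schema = default_schema()) {
  data <- as.data.frame(data)
  if (nrow(data) < 1) stop("cohort must contain at least one record", call. = FALSE)
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(data), names(schema))
  if (length(extra)) {
    stop("schema error: unknown column(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  data <- data[names(schema)]
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(data)) {
    stop("outcome length must match record count", call. = FALSE)
  }
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L))) {
    stop("outcome must be complete and binary 0/1", call. = FALSE)
  }
  for (v in schema) {
    col <- data[[v$name]]
    if (v$kind == "categorical") {
      if (is.factor(col)) col <- as.character(col)
      bad <- which(!col %in% v$categories)
      if (length(bad)) {
        stop(sprintf("validation error: row %d, column '%s': unknown label '%s'",
                     bad[1], v$name, col[bad[1]]), call. = FALSE)
      }
      data[[v$name]] <- factor(col, levels = v$categories)
    } else {
      col <- as.numeric(col)
      if (anyNA(col)) {
        stop(sprintf("validation error: missing value in column '%s' (row %d)",
                     v$name, which(is.na(col))[1]), call. = FALSE)
      }
      if (v$kind == "binary" && !all(col %in% c(0, 1))) {
        bad <- which(!col %in% c(0, 1))[1]
        stop(sprintf("validation error: row %d, column '%s': binary value %s",
                     bad, v$name, col[bad]), call. = FALSE)
      }
      bad <- which(col < v$lower | col > v$upper)
      if (length(bad)) {
        stop(sprintf(
          "validation error: row %d, column '%s': value %g outside [%g, %g]",
          bad[1], v$name, col[bad[1]], v$lower, v$upper), call. = FALSE)
      }
      data[[v$name]] <- col
    }
  }
  structure(list(data = data, outcome = outcome, schema = schema),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d records, %d predictors, %d events (%.1f%%)\n",
              nrow(x$data), length(x$schema), sum(x$outcome),
              100 * mean(x$outcome)))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) c(nrow(x$data), length(x$schema))

#' Number of records in a cohort
#' @param table a `cohort_table`.
#' @return integer record count.
#' @export
n_records <- function(table) nrow(table$data)

#' Subset a cohort table by row indices
#' @param table a `cohort_table`.
#' @param idx integer row indices.
#' @return a `cohort_table` with the selected records.
#' @export
cohort_subset <- function(table, idx) {
  structure(list(data = table$data[idx, , drop = FALSE],
                 outcome = table$outcome[idx],
                 schema = table$schema),
            class = "cohort_table")
}

#' Load a cohort from CSV + schema
#'
#' Reads a UTF-8 CSV with a header row (`.` decimal separator) and
#' validates it against the schema. The outcome column (default
#' `"occlusion"`) is split off from the predictors.
#'
#' @param path CSV file path.
#' @param schema a `cohort_schema` or path to a JSON schema sidecar.
#' @param outcome_col name of the outcome column in the CSV.
#' @return a `cohort_table`.
#' @export
load_cohort <- function(path, schema = default_schema(),
                        outcome_col = "occlusion") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema)) schema <- read_schema(schema)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!outcome_col %in% names(df)) {
    stop("schema error: outcome column '", outcome_col, "' not found",
         call. = FALSE)
  }
  outcome <- df[[outcome_col]]
  df[[outcome_col]] <- NULL
  cohort_table(df, outcome, schema)
}

#' Write a cohort to CSV (round-trip safe)
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @param outcome_col outcome column name to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, outcome_col = "occlusion") {
  df <- table$data
  for (nm in names(df)) {
    if (is.factor(df[[nm]])) {
      df[[nm]] <- as.character(df[[nm]])
    } else if (is.double(df[[nm]])) {
      # 17 significant digits make the decimal round-trip bit-exact
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df[[outcome_col]] <- table$outcome
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
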