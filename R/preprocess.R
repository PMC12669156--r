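#' Fit preprocessing parameters on training data
#'
#' Continuous and count variables are standardised to z-scores with the
#' training mean and SD; binaries pass through as 0/1; categorical
#' variables are one-hot encoded with the first schema level as reference.
#' Parameters are frozen for test-time reuse: applying them to new data
#' never re-estimates anything.
#'
#' @param train a `cohort_table` of training records.
#' @return an object of class `preprocess_params`.
#' @export
fit_preprocess <- function(train) {
  params <- lapply(train$schema, function(v) {
    if (v$kind == "categorical") {
      list(kind = "categorical", levels = v$categories)
    } else if (v$kind == "binary") {
      list(kind = "binary")
    } else {
      x <- train$data[[v$name]]
      s <- stats::sd(x)
      list(kind = "continuous", mean = mean(x), sd = if (s > 0) s else 1)
    }
  })
  names(params) <- names(train$schema)
  # column name -> source variable map, used to apply variable-level masks
  cols <- character(0); src <- character(0)
  for (v in train$schema) {
    if (v$kind == "categorical") {
      nm <- paste0(v$name, "=", v$categories[-1])
      cols <- c(cols, nm); src <- c(src, rep(v$name, length(nm)))
    } else {
      cols <- c(cols, v$name); src <- c(src, v$name)
    }
  }
  structure(list(params = params, columns = cols, column_var = src),
            class = "preprocess_params")
}

#' Apply frozen preprocessing to a cohort
#'
#' @param params a `preprocess_params` from [fit_preprocess()].
#' @param table a `cohort_table` to transform.
#' @return numeric matrix with one row per record; column names follow
#'   `variable` or `variable=level` for one-hot indicators.
#' @export
apply_preprocess <- function(params, table) {
  stopifnot(inherits(params, "preprocess_params"))
  n <- nrow(table$data)
  out <- matrix(0, n, length(params$columns),
                dimnames = list(NULL, params$columns))
  j <- 1L
  for (nm in names(params$params)) {
    p <- params$params[[nm]]
    x <- table$data[[nm]]
    if (is.null(x)) stop("column '", nm, "' absent at apply time", call. = FALSE)
    if (p$kind == "categorical") {
      x <- as.character(x)
      unseen <- setdiff(unique(x), p$levels)
      if (length(unseen)) {
        stop("unseen category '", unseen[1], "' in column '", nm, "'",
             call. = FALSE)
      }
      for (lev in p$levels[-1]) {
        out[, j] <- as.numeric(x == lev)
        j <- j + 1L
      }
    } else if (p$kind == "binary") {
      out[, j] <- as.numeric(x)
      j <- j + 1L
    } else {
      out[, j] <- (as.numeric(x) - p$mean) / p$sd
      j <- j + 1L
    }
  }
  out
}

# restrict a preprocessed matrix to the variables switched on in a mask
mask_columns <- function(params, mask_bits, var_names) {
  keep_vars <- var_names[as.logical(mask_bits)]
  params$column_var %in% keep_vars
}
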