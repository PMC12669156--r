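#' Variable schema for a patient cohort
#'
#' A schema describes each cohort variable: its name, measurement kind
#' (which determines the summary statistic and baseline test applied to
#' it), units, categories (for categorical variables) and optional physical
#' bounds used for validation.
#'
#' @param name variable name (unique identifier).
#' @param kind one of `"continuous_normal"`, `"continuous_skewed"`,
#'   `"binary"`, `"categorical"`, `"count"`.
#' @param units free-text units (e.g. `"years"`, `"mm"`, `"mg/L"`).
#' @param categories ordered character vector of levels (categorical only;
#'   the first level is the one-hot reference).
#' @param lower,upper optional physical bounds enforced at validation.
#' @return an object of class `variable_schema`.
#' @export
variable_schema <- function(name, kind, units = "", categories = NULL,
                            lower = -Inf, upper = Inf) {
  kinds <- c("continuous_normal", "continuous_skewed", "binary",
             "categorical", "count")
  if (!kind %in% kinds) {
    stop("unknown variable kind '", kind, "'", call. = FALSE)
  }
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2) {
      stop("categorical variable '", name, "' needs >= 2 categories",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, units = units,
         categories = categories, lower = lower, upper = upper),
    class = "variable_schema"
  )
}

#' Cohort schema: an ordered list of variable schemas
#'
#' @param ... `variable_schema` objects (or a single list of them).
#' @return object of class `cohort_schema`.
#' @export
cohort_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1 && is.list(vars[[1]]) &&
      !inherits(vars[[1]], "variable_schema")) {
    vars <- vars[[1]]
  }
  nm <- vapply(vars, function(v) v$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate variable names in schema", call. = FALSE)
  names(vars) <- nm
  structure(vars, class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort schema with", length(x), "variables\n")
  for (v in x) {
    cat(sprintf("  %-18s %-18s %s\n", v$name, v$kind,
                if (v$kind == "categorical") {
                  paste(v$categories, collapse = "/")
                } else {
                  v$units
                }))
  }
  invisible(x)
}

#' Default predictor schema of the stent-occlusion cohort
#'
#' The 22 predictors recorded for every patient: demographics and etiology,
#' perioperative/stent parameters, postoperative anticoagulation and first
#' coagulation panel, and 30-day recanalization rates of the external iliac
#' (EIV), common femoral (CFV) and femoral (FV) veins. Recanalization rates
#' are bounded to [0, 100] %; stent geometry and anthropometrics must be
#' positive.
#'
#' @return a `cohort_schema` of the 22 predictors.
#' @export
default_schema <- function() {
  cohort_schema(
    variable_schema("sex_male", "binary"),
    variable_schema("age", "continuous_normal", "years", lower = 0),
    variable_schema("bmi", "continuous_skewed", "kg/m2", lower = 0),
    variable_schema("hospital_stay", "continuous_skewed", "days", lower = 0),
    variable_schema("etiology", "categorical",
                    categories = c("PTS", "DVT", "Cockett", "DVT + Cockett",
                                   "DVT + Cockett + PE")),
    variable_schema("smoking", "binary"),
    variable_schema("av_fistula", "binary"),
    variable_schema("surgery_time", "continuous_normal", "minutes", lower = 0),
    variable_schema("stent_number", "count", lower = 1),
    variable_schema("stent_length", "continuous_normal", "mm", lower = 0),
    variable_schema("stent_diameter", "continuous_normal", "mm", lower = 0),
    variable_schema("ivc_extension", "continuous_skewed", "mm", lower = 0),
    variable_schema("anticoagulation", "categorical",
                    categories = c("warfarin", "NOAC", "none")),
    variable_schema("compression", "binary"),
    variable_schema("pt", "continuous_normal", "s", lower = 0),
    variable_schema("aptt", "continuous_normal", "s", lower = 0),
    variable_schema("fib", "continuous_skewed", "g/L", lower = 0),
    variable_schema("d_dimer", "continuous_skewed", "mg/L", lower = 0),
    variable_schema("crp", "continuous_skewed", "mg/L", lower = 0),
    variable_schema("eiv_recan", "continuous_normal", "%", lower = 0, upper = 100),
    variable_schema("cfv_recan", "continuous_skewed", "%", lower = 0, upper = 100),
    variable_schema("fv_recan", "continuous_skewed", "%", lower = 0, upper = 100)
  )
}

#' Read / write a schema as a JSON sidecar
#'
#' @param schema a `cohort_schema`.
#' @param path JSON file path.
#' @return `read_schema` returns a `cohort_schema`; `write_schema` the path,
#'   invisibly.
#' @export
write_schema <- function(schema, path) {
  lst <- lapply(unclass(schema), function(v) {
    out <- list(name = v$name, kind = v$kind, units = v$units)
    if (!is.null(v$categories)) out$categories <- v$categories
    if (is.finite(v$lower)) out$lower <- v$lower
    if (is.finite(v$upper)) out$upper <- v$upper
    out
  })
  jsonlite::write_json(unname(lst), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @param path JSON file path.
#' @export
read_schema <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  cohort_schema(lapply(lst, function(v) {
    variable_schema(v$name, v$kind, v$units %||% "",
                    categories = if (!is.null(v$categories)) {
                      unlist(v$categories)
                    },
                    lower = v$lower %||% -Inf, upper = v$upper %||% Inf)
  }))
}
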