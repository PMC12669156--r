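#' Single-patient risk report
#'
#' Scores one validated patient record with a fitted AutoML model and
#' attaches per-feature Shapley contributions (exact tree attributions on
#' the log-odds scale, aggregated to source variables) computed against a
#' training background. The probability is reported on the 0-100% scale.
#'
#' @param model an `automl_fit`.
#' @param patient one-row data.frame (or list) of predictor values, or a
#'   one-record `cohort_table`.
#' @param schema schema used to validate a bare record.
#' @return object of class `risk_report`: `probability` (percent),
#'   `contributions` (named, log-odds scale), `base_value`, `input`.
#' @export
predict_risk <- function(model, patient, schema = default_schema()) {
  if (!inherits(patient, "cohort_table")) {
    patient <- as.data.frame(patient, stringsAsFactors = FALSE,
                             check.names = FALSE)
    missing_cols <- setdiff(names(schema), names(patient))
    if (length(missing_cols)) {
      stop("missing required feature(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    patient <- cohort_table(patient, outcome = 0L, schema = schema)
  }
  p <- stats::predict(model, patient)
  sh <- shapley_values(model, patient)
  keep <- mask_columns(model$preprocess, model$mask, model$var_names)
  col_var <- model$preprocess$column_var[keep]
  imp <- vapply(unique(col_var), function(v) {
    sum(sh$phi[1, col_var == v])
  }, numeric(1))
  structure(list(probability = 100 * as.numeric(p[1]),
                 contributions = imp, base_value = sh$base_value,
                 input = patient$data[1, , drop = FALSE],
                 model_features = selected_features(model)),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("risk_report: occlusion probability %.1f%%\n", x$probability))
  ord <- order(-abs(x$contributions))
  for (i in ord) {
    cat(sprintf("  %-18s %+0.4f\n", names(x$contributions)[i],
                x$contributions[i]))
  }
  invisible(x)
}

#' Run the full analysis pipeline and write its artifact bundle
#'
#' Simulate-or-load, split, fit the model zoo, evaluate, explain, report:
#' writes the baseline comparison table, the CV and test metric tables,
#' ROC/PR inputs, DCA and calibration curves, the LASSO path/CV summary,
#' SHAP importance, and a run manifest (seeds, budgets, selected features,
#' hyperparameters) to `out_dir`.
#'
#' @param out_dir output directory (created if absent).
#' @param cohort a `cohort_table`; if `NULL` a synthetic cohort of
#'   `n` records is simulated from [default_spec()].
#' @param n synthetic cohort size when simulating.
#' @param seed master seed.
#' @param train_fraction split ratio.
#' @param specs model zoo specs (see [compare_models()]).
#' @param automl an `automl_config`; default uses the master seed.
#' @return invisibly, a named list of the written artifact paths.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, n = 826L, seed = 1L,
                         train_fraction = 0.8,
                         specs = lapply(c("LR", "XGBoost", "AutoML"),
                                        model_spec),
                         automl = automl_config(plan = cv_plan(seed = seed),
                                                seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    spec <- default_spec()
    cohort <- sample_cohort(spec, n, seed = seed)
  }
  split <- stratified_split(cohort, train_fraction, seed = seed)
  train <- cohort_subset(cohort, split$train_index)
  test <- cohort_subset(cohort, split$test_index)
  paths <- list()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  w(baseline_table(cohort, split), "baseline_table.csv")
  cmp <- compare_models(train, test, specs = specs,
                        plan = automl$plan, automl = automl, seed = seed)
  w(cmp$cv, "metrics_cv.csv")
  w(cmp$test, "metrics_test.csv")
  fit <- fit_automl(train, automl)
  p_test <- stats::predict(fit, test)
  w(data.frame(y = test$outcome, p = p_test), "test_predictions.csv")
  w(as.data.frame(dca_curve(test$outcome, p_test)), "dca_curve.csv")
  cal <- brier_calibration(test$outcome, p_test)
  w(cal$bins, "calibration_curve.csv")
  pp <- fit_preprocess(train)
  X <- apply_preprocess(pp, train)
  path <- lasso_logistic_path(X, train$outcome, nlambda = 60,
                              seed = seed)
  w(data.frame(lambda = path$lambda, cv_mean = path$cv_mean,
               cv_se = path$cv_se, nonzero = path$nonzero),
    "lasso_cv.csv")
  sh <- shapley_values(fit, train)
  keep <- mask_columns(pp, fit$mask, fit$var_names)
  imp <- shap_importance(sh, column_var = pp$column_var[keep])
  w(imp, "shap_importance.csv")
  manifest <- list(seed = seed, n = n_records(cohort),
                   train_fraction = train_fraction,
                   folds = automl$plan$folds,
                   selected_features = selected_features(fit),
                   hyperparams = fit$hyperparams[names(fit$hyperparams)],
                   cv_score = fit$cv_score,
                   test_brier = cal$brier,
                   test_roc_auc = roc_auc(test$outcome, p_test),
                   lasso_lambda_1se = path$lambda_1se,
                   lasso_selected = path$selected)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- mpath
  invisible(paths)
}
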