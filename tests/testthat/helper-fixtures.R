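# Shared fixtures; expensive objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

# calibrated generator spec of the emulated study population
the_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- default_spec()
  .fixtures$spec
}

# canonical synthetic cohort (study size, fixed seed)
the_cohort <- function(n = 826L, seed = 20250826L) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- sample_cohort(the_spec(), n, seed = seed)
  }
  .fixtures[[key]]
}

# small continuous-only schema for toy cohorts
toy_schema <- function(d, lower = -Inf) {
  cohort_schema(lapply(seq_len(d), function(j) {
    variable_schema(paste0("f", j), "continuous_normal", lower = lower)
  }))
}

# toy cohort: outcome driven by features 1 and 3 (feature 1 only if d < 3)
toy_signal_cohort <- function(n = 300L, d = 6L, seed = 1L, beta = 1.6) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  eta <- beta * X[, 1] - 0.8
  if (d >= 3) eta <- eta - beta * X[, 3]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(d))
  cohort_table(df, y, toy_schema(d))
}

# small, fast AutoML budget for unit tests
tiny_automl_config <- function(seed = 1L, folds = 3L) {
  automl_config(plan = cv_plan(folds, seed = seed + 1000L), seed = seed,
                stage1_pop = 6L, stage1_iters = 4L,
                stage2_pop = 6L, stage2_iters = 3L,
                hp_space = hyperparam_space(nrounds = c(20, 60)),
                hp0 = list(nrounds = 30L, max_depth = 3L, eta = 0.15,
                           subsample = 0.9, min_child_weight = 5, lambda = 1))
}

# study-scale-down AutoML configuration used for the recovery checks:
# the cohort is kept at the study size (826) while the optimizer budgets
# and ensemble sizes are reduced to desk scale
recovery_automl_config <- function(seed) {
  automl_config(
    plan = cv_plan(3L, seed = stentrisk:::derive_seed(seed, 9)),
    seed = seed,
    stage1_pop = 12L, stage1_iters = 10L,
    stage2_pop = 8L, stage2_iters = 6L,
    hp_space = hyperparam_space(nrounds = c(30, 150)),
    hp0 = list(nrounds = 80L, max_depth = 4L, eta = 0.1,
               subsample = 0.9, min_child_weight = 5, lambda = 1))
}

# variable-level SHAP importance of a fitted AutoML model
automl_importance <- function(fit, table) {
  sh <- shapley_values(fit, table)
  keep <- stentrisk:::mask_columns(fit$preprocess, fit$mask, fit$var_names)
  shap_importance(sh, column_var = fit$preprocess$column_var[keep])
}
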