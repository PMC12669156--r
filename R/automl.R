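#' Cross-validation plan
#'
#' @param folds number of folds (>= 2, default 5).
#' @param seed integer seed for the stratified fold assignment.
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(folds = 5L, seed = 1L) {
  stopifnot(folds >= 2)
  structure(list(folds = as.integer(folds), stratified = TRUE,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# stratified fold ids; every fold receives members of both classes
make_folds <- function(y, plan) {
  with_seed(plan$seed, {
    ids <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < plan$folds) {
        stop("class ", cls, " has fewer members (", length(idx),
             ") than folds", call. = FALSE)
      }
      ids[idx] <- sample(rep_len(seq_len(plan$folds), length(idx)))
    }
    ids
  })
}

#' Decode a real-valued position into a feature mask
#'
#' Sigmoid transfer: bit i is switched on with probability
#' `S(position_i) = 1 / (1 + exp(-position_i))`, drawing from the current
#' RNG stream. An all-zero outcome is rescued by flipping the bit with the
#' largest transfer probability, so a usable mask always results.
#'
#' @param position numeric position vector.
#' @return logical mask vector of the same length.
#' @export
mask_from_position <- function(position) {
  s <- 1 / (1 + exp(-position))
  bits <- stats::runif(length(position)) < s
  if (!any(bits)) bits[which.max(s)] <- TRUE
  bits
}

#' Cross-validated fitness of a (mask, hyperparameters) pair
#'
#' Mean out-of-fold ROC-AUC over stratified folds, minus a parsimony
#' penalty of `penalty * (bits set / total bits)`. Inside each fold the
#' preprocessing is fitted on the fold-train records only, SMOTE rebalances
#' the fold-train only, and the AUC is measured on the untouched
#' fold-validation records — no information crosses the fold boundary.
#'
#' @param table training `cohort_table`.
#' @param mask logical feature mask over the schema predictors.
#' @param hp hyperparameter list (see [default_hyperparams()]).
#' @param plan a `cv_plan`.
#' @param penalty parsimony penalty weight (default 0.01).
#' @param smote_k SMOTE neighbour count.
#' @param smote_target minority target per fold (`NULL` = near parity).
#' @return scalar fitness (higher is better).
#' @export
cv_fitness <- function(table, mask, hp, plan = cv_plan(), penalty = 0.01,
                       smote_k = 5L, smote_target = NULL) {
  ctx <- cv_context(table, plan)
  cv_fitness_ctx(ctx, mask, hp, penalty, smote_k, smote_target)
}

# fold bookkeeping shared by every fitness evaluation of a search: fold
# membership and per-fold preprocessed matrices are mask/hp independent,
# so they are built once. Preprocessing is still fitted on fold-train rows
# only.
cv_context <- function(table, plan) {
  y <- table$outcome
  folds <- make_folds(y, plan)
  per_fold <- lapply(seq_len(plan$folds), function(f) {
    tr_idx <- which(folds != f); va_idx <- which(folds == f)
    tr <- cohort_subset(table, tr_idx)
    pp <- fit_preprocess(tr)
    list(pp = pp,
         Xtr = apply_preprocess(pp, tr),
         Xva = apply_preprocess(pp, cohort_subset(table, va_idx)),
         ytr = y[tr_idx], yva = y[va_idx])
  })
  list(folds = per_fold, plan = plan, var_names = names(table$schema))
}

cv_fitness_ctx <- function(ctx, mask, hp, penalty = 0.01, smote_k = 5L,
                           smote_target = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask", call. = FALSE)
  plan <- ctx$plan
  aucs <- vapply(seq_along(ctx$folds), function(f) {
    fd <- ctx$folds[[f]]
    keep <- mask_columns(fd$pp, mask, ctx$var_names)
    Xtr <- fd$Xtr[, keep, drop = FALSE]
    sm <- smote(Xtr, fd$ytr, k = smote_k, target_minority = smote_target,
                seed = derive_seed(plan$seed, f))
    model <- fit_gbt(sm$X, sm$y, hp, seed = derive_seed(plan$seed, 100 + f))
    roc_auc(fd$yva, predict_gbt(model, fd$Xva[, keep, drop = FALSE]))
  }, numeric(1))
  mean(aucs) - penalty * sum(mask) / length(mask)
}

#' Stage 1: metaheuristic feature-subset selection
#'
#' ISequoiaOA searches the discrete mask space (positions decoded through
#' the sigmoid transfer of [mask_from_position()]) maximising the
#' cross-validated fitness at fixed base hyperparameters.
#'
#' @param table training `cohort_table`.
#' @param hp0 base hyperparameters used during the search.
#' @param plan a `cv_plan`.
#' @param opt_config an `optimizer_config` (budget of the search).
#' @param ... passed to [cv_fitness()].
#' @return logical feature mask with attribute `"fitness"`.
#' @export
stage1_select <- function(table, hp0 = default_hyperparams(),
                          plan = cv_plan(),
                          opt_config = optimizer_config(pop_size = 10L,
                                                        max_iters = 15L),
                          ...) {
  d <- length(table$schema)
  ctx <- cv_context(table, plan)
  if (d == 1L) {
    m <- TRUE
    attr(m, "fitness") <- cv_fitness_ctx(ctx, m, hp0, ...)
    return(m)
  }
  space <- search_space(rep(-4, d), rep(4, d), discrete = TRUE)
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    bits <- mask_from_position(pos)
    key <- paste(as.integer(bits), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- -cv_fitness_ctx(ctx, bits, hp0, ...)
    cache[[key]] <- val
    val
  }
  res <- iseq_optimize(objective, space, opt_config)
  # decode the best position deterministically: best recorded mask
  keys <- ls(cache)
  vals <- vapply(keys, function(k) cache[[k]], numeric(1))
  best_key <- keys[which.min(vals)]
  mask <- as.logical(as.integer(strsplit(best_key, "")[[1]]))
  attr(mask, "fitness") <- -min(vals)
  mask
}

#' Stage 2: metaheuristic hyperparameter tuning at a fixed mask
#'
#' ISequoiaOA searches the unit box mapped onto the hyperparameter
#' intervals (integer parameters rounded at evaluation). The default
#' hyperparameter point is always evaluated too, so the tuned score never
#' falls below the default's.
#'
#' @param table training `cohort_table`.
#' @param mask logical feature mask from stage 1.
#' @param space a `hyperparam_space`.
#' @param plan a `cv_plan`.
#' @param opt_config an `optimizer_config`.
#' @param ... passed to [cv_fitness()].
#' @return hyperparameter list with attribute `"cv_score"`.
#' @export
stage2_tune <- function(table, mask, space = hyperparam_space(),
                        plan = cv_plan(),
                        opt_config = optimizer_config(pop_size = 10L,
                                                      max_iters = 15L),
                        ...) {
  ubox <- search_space(rep(0, length(space)), rep(1, length(space)))
  ctx <- cv_context(table, plan)
  objective <- function(u) {
    -cv_fitness_ctx(ctx, mask, position_to_hp(u, space), ...)
  }
  res <- iseq_optimize(objective, ubox, opt_config)
  tuned <- position_to_hp(res$best_position, space)
  tuned_score <- -res$best_fitness
  hp0 <- default_hyperparams()
  if (hp_inside(hp0, space)) {
    def_score <- cv_fitness_ctx(ctx, mask, hp0, ...)
    if (def_score > tuned_score) {
      tuned <- hp0
      tuned_score <- def_score
    }
  }
  attr(tuned, "cv_score") <- tuned_score
  tuned
}

#' AutoML engine configuration
#'
#' @param plan a `cv_plan`.
#' @param seed master seed driving both optimisation stages.
#' @param stage1_pop,stage1_iters budget of the feature-selection stage.
#' @param stage2_pop,stage2_iters budget of the tuning stage.
#' @param hp_space a `hyperparam_space`.
#' @param hp0 base hyperparameters for stage 1.
#' @param penalty parsimony penalty weight.
#' @param smote_k,smote_target SMOTE settings (see [smote()]).
#' @return list of class `automl_config`.
#' @export
automl_config <- function(plan = cv_plan(), seed = 1L,
                          stage1_pop = 12L, stage1_iters = 15L,
                          stage2_pop = 10L, stage2_iters = 12L,
                          hp_space = hyperparam_space(),
                          hp0 = default_hyperparams(),
                          penalty = 0.01, smote_k = 5L, smote_target = NULL) {
  structure(list(plan = plan, seed = as.integer(seed),
                 stage1_pop = stage1_pop, stage1_iters = stage1_iters,
                 stage2_pop = stage2_pop, stage2_iters = stage2_iters,
                 hp_space = hp_space, hp0 = hp0, penalty = penalty,
                 smote_k = smote_k, smote_target = smote_target),
            class = "automl_config")
}

#' Fit the dual-stage AutoML model
#'
#' Runs stage 1 (feature selection) then stage 2 (hyperparameter tuning
#' conditioned on the stage-1 mask), then refits the gradient-boosted-tree
#' learner on the full, SMOTE-rebalanced training table with the selected
#' mask and hyperparameters. Preprocessing parameters are frozen from the
#' training table for test-time reuse.
#'
#' @param table training `cohort_table`.
#' @param config an `automl_config`.
#' @return object of class `automl_fit`: `mask`, `hyperparams`,
#'   `preprocess`, `learner`, `cv_score`, `var_names`.
#' @export
fit_automl <- function(table, config = automl_config()) {
  plan <- config$plan
  mask <- stage1_select(
    table, hp0 = config$hp0, plan = plan,
    opt_config = optimizer_config(pop_size = config$stage1_pop,
                                  max_iters = config$stage1_iters,
                                  seed = derive_seed(config$seed, 1)),
    penalty = config$penalty, smote_k = config$smote_k,
    smote_target = config$smote_target)
  hp <- stage2_tune(
    table, mask, space = config$hp_space, plan = plan,
    opt_config = optimizer_config(pop_size = config$stage2_pop,
                                  max_iters = config$stage2_iters,
                                  seed = derive_seed(config$seed, 2)),
    penalty = config$penalty, smote_k = config$smote_k,
    smote_target = config$smote_target)
  pp <- fit_preprocess(table)
  var_names <- names(table$schema)
  keep <- mask_columns(pp, mask, var_names)
  X <- apply_preprocess(pp, table)[, keep, drop = FALSE]
  sm <- smote(X, table$outcome, k = config$smote_k,
              target_minority = config$smote_target,
              seed = derive_seed(config$seed, 3))
  learner <- fit_gbt(sm$X, sm$y, hp, seed = derive_seed(config$seed, 4))
  structure(list(mask = as.logical(mask), hyperparams = hp,
                 preprocess = pp, learner = learner,
                 cv_score = attr(hp, "cv_score"),
                 var_names = var_names, seed = config$seed),
            class = "automl_fit")
}

#' @export
print.automl_fit <- function(x, ...) {
  cat(sprintf("automl_fit: %d/%d features selected, CV score %.4f\n",
              sum(x$mask), length(x$mask), x$cv_score))
  cat("  features:", paste(x$var_names[x$mask], collapse = ", "), "\n")
  invisible(x)
}

#' Predict occlusion probabilities from a fitted AutoML model
#'
#' @param object an `automl_fit`.
#' @param table a `cohort_table` of new records.
#' @param ... unused.
#' @return probability vector in \[0, 1\].
#' @export
predict.automl_fit <- function(object, table, ...) {
  keep <- mask_columns(object$preprocess, object$mask, object$var_names)
  X <- apply_preprocess(object$preprocess, table)[, keep, drop = FALSE]
  predict_gbt(object$learner, X)
}

#' Selected feature names of a fitted AutoML model
#' @param fit an `automl_fit`.
#' @return character vector of selected predictor names.
#' @export
selected_features <- function(fit) fit$var_names[fit$mask]
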