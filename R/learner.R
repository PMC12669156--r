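# Gradient-boosted tree learner behind the AutoML engine (xgboost backend).
# Single-threaded and seeded so that identical inputs reproduce identical
# models.

#' Default gradient-boosted-tree hyperparameters
#'
#' @return named list: `nrounds`, `max_depth`, `eta`, `subsample`,
#'   `min_child_weight`, `lambda`.
#' @export
default_hyperparams <- function() {
  list(nrounds = 150L, max_depth = 4L, eta = 0.1, subsample = 0.9,
       min_child_weight = 5, lambda = 1)
}

#' Hyperparameter search space of the tuning stage
#'
#' Box intervals over ensemble size, tree depth, learning rate, row
#' subsampling, minimum leaf weight and L2 regularisation.
#'
#' @param nrounds,max_depth,eta,subsample,min_child_weight,lambda numeric
#'   `c(lower, upper)` intervals.
#' @return object of class `hyperparam_space`.
#' @export
hyperparam_space <- function(nrounds = c(50, 500), max_depth = c(2, 8),
                             eta = c(0.01, 0.3), subsample = c(0.5, 1),
                             min_child_weight = c(1, 20), lambda = c(0, 10)) {
  sp <- list(nrounds = nrounds, max_depth = max_depth, eta = eta,
             subsample = subsample, min_child_weight = min_child_weight,
             lambda = lambda)
  for (nm in names(sp)) stopifnot(length(sp[[nm]]) == 2, sp[[nm]][1] < sp[[nm]][2])
  structure(sp, class = "hyperparam_space")
}

# map an unconstrained [0,1]^6 position into a concrete hyperparameter point;
# integer-valued parameters are rounded at evaluation time
position_to_hp <- function(u, space) {
  hp <- list()
  for (i in seq_along(space)) {
    nm <- names(space)[i]
    lo <- space[[i]][1]; hi <- space[[i]][2]
    val <- lo + clip(u[i], 0, 1) * (hi - lo)
    if (nm %in% c("nrounds", "max_depth")) val <- as.integer(round(val))
    hp[[nm]] <- val
  }
  hp
}

hp_inside <- function(hp, space) {
  all(vapply(names(space), function(nm) {
    hp[[nm]] >= space[[nm]][1] && hp[[nm]] <= space[[nm]][2]
  }, logical(1)))
}

fit_gbt <- function(X, y, hp, seed = 1L) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  params <- list(objective = "binary:logistic",
                 max_depth = hp$max_depth, eta = hp$eta,
                 subsample = hp$subsample,
                 min_child_weight = hp$min_child_weight,
                 lambda = hp$lambda,
                 nthread = 1, seed = as.integer(seed))
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$nrounds, verbose = 0)
}

predict_gbt <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
}
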