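#' Model specification for the comparison zoo
#'
#' The six comparison models: logistic regression (LR), support vector
#' machine with Platt-calibrated probabilities (SVM), discrete AdaBoost
#' over depth-1/2 trees (AdaBoost), gradient boosting with depth-wise
#' growth (XGBoost), gradient boosting with leaf-wise growth (LightGBM
#' configuration), and the dual-stage AutoML framework. Comparators run at
#' library defaults; only AutoML tunes itself.
#'
#' @param name one of `"LR"`, `"SVM"`, `"AdaBoost"`, `"XGBoost"`,
#'   `"LightGBM"`, `"AutoML"`.
#' @param hyperparams optional named overrides.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, hyperparams = list()) {
  name <- match.arg(name, c("LR", "SVM", "AdaBoost", "XGBoost",
                            "LightGBM", "AutoML"))
  structure(list(name = name, hyperparams = hyperparams),
            class = "model_spec")
}

#' Train one comparison model
#'
#' @param spec a `model_spec`.
#' @param X standardized numeric feature matrix.
#' @param y binary outcome vector.
#' @param seed integer seed for stochastic learners.
#' @return object of class `fitted_model`.
#' @export
train_model <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  hp <- spec$hyperparams
  fit <- switch(spec$name,
    LR = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    SVM = with_seed(seed, {
      e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE,
                 kernel = hp$kernel %||% "radial",
                 cost = hp$cost %||% 1)
    }),
    AdaBoost = with_seed(seed, {
      adaboost_fit(X, y, n_rounds = hp$n_rounds %||% 100L,
                   maxdepth = hp$maxdepth %||% 2L)
    }),
    XGBoost = fit_gbt(X, y, list(nrounds = hp$nrounds %||% 100L,
                                 max_depth = hp$max_depth %||% 6L,
                                 eta = hp$eta %||% 0.3,
                                 subsample = hp$subsample %||% 1,
                                 min_child_weight = hp$min_child_weight %||% 1,
                                 lambda = hp$lambda %||% 1),
                      seed = seed),
    LightGBM = {
      # leaf-wise (lossguide) growth with 31 leaves: the defining LightGBM
      # configuration, realised through the xgboost histogram backend
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      params <- list(objective = "binary:logistic",
                     tree_method = "hist", grow_policy = "lossguide",
                     max_leaves = hp$max_leaves %||% 31L, max_depth = 0L,
                     eta = hp$eta %||% 0.1,
                     min_child_weight = hp$min_child_weight %||% 1,
                     lambda = hp$lambda %||% 1,
                     nthread = 1, seed = as.integer(seed))
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds %||% 100L, verbose = 0)
    },
    AutoML = stop("AutoML trains from a cohort_table through fit_automl()",
                  call. = FALSE)
  )
  structure(list(name = spec$name, fit = fit, n_features = ncol(X)),
            class = "fitted_model")
}

#' Predict event probabilities from a fitted comparison model
#'
#' @param model a `fitted_model` from [train_model()].
#' @param X numeric feature matrix on the training standardisation.
#' @return probability vector in \[0, 1\].
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  p <- switch(model$name,
    LR = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      stats::predict(model$fit, newdata = df, type = "response")
    },
    SVM = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    AdaBoost = adaboost_predict(model$fit, X),
    XGBoost = predict_gbt(model$fit, X),
    LightGBM = predict_gbt(model$fit, X)
  )
  unname(clip(as.numeric(p), 0, 1))
}

# ---- discrete AdaBoost (SAMME) over shallow rpart trees ------------------

adaboost_fit <- function(X, y, n_rounds = 100L, maxdepth = 2L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(maxdepth = maxdepth,
                                                        cp = 0, minsplit = 5,
                                                        xval = 0))
    pred <- as.integer(as.character(stats::predict(tree, df, type = "class")))
    hm <- ifelse(pred == 1, 1, -1)
    err <- sum(w * (hm != yy))
    err <- clip(err, 1e-10, 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break
    w <- w * exp(-alpha * yy * hm)
    w <- w / sum(w)
    stumps[[m]] <- tree; alphas[m] <- alpha
    if (err < 1e-9) break
  }
  list(trees = stumps, alphas = alphas, p = ncol(X))
}

adaboost_predict <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(fit$p))
  F <- rep(0, nrow(X))
  for (m in seq_along(fit$trees)) {
    pred <- as.integer(as.character(stats::predict(fit$trees[[m]], df,
                                                   type = "class")))
    F <- F + fit$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * F))  # logistic link on the boosting margin
}

#' Compare the six models on a train/test split
#'
#' Reports the seven-metric panel (PRE, SEN, SPE, ACC, F1, ROC-AUC,
#' PR-AUC) twice per model: on pooled out-of-fold cross-validation
#' predictions over the training table and on the held-out test table.
#' Comparators use the full standardized feature set; AutoML runs its own
#' dual-stage selection. Under `paper_mode`, SMOTE is additionally applied
#' to the evaluation partitions (CV validation folds and the test set)
#' before metrics are computed — a protocol that rebalances the evaluation
#' data itself and is never the default.
#'
#' @param train,test `cohort_table`s (disjoint records).
#' @param specs list of `model_spec`s.
#' @param plan a `cv_plan`.
#' @param automl an `automl_config` used when an AutoML spec is present.
#' @param threshold decision threshold for the confusion metrics.
#' @param seed integer seed.
#' @param paper_mode apply SMOTE to evaluation partitions as well.
#' @return list with data.frames `cv` and `test` (one row per model,
#'   seven metric columns).
#' @export
compare_models <- function(train, test,
                           specs = lapply(c("LR", "SVM", "AdaBoost",
                                            "XGBoost", "LightGBM", "AutoML"),
                                          model_spec),
                           plan = cv_plan(), automl = automl_config(plan = plan),
                           threshold = 0.5, seed = 1L, paper_mode = FALSE) {
  pp <- fit_preprocess(train)
  Xtr <- apply_preprocess(pp, train)
  Xte <- apply_preprocess(pp, test)
  ytr <- train$outcome; yte <- test$outcome
  folds <- make_folds(ytr, plan)

  eval_partition <- function(y, p) {
    metrics_report(y, p, threshold)
  }
  maybe_augment <- function(X, y, stream) {
    if (!paper_mode) return(list(X = X, y = y))
    sm <- smote(X, y, seed = derive_seed(seed, stream))
    list(X = sm$X, y = sm$y)
  }

  cv_rows <- list(); te_rows <- list()
  for (spec in specs) {
    if (spec$name == "AutoML") {
      fit <- fit_automl(train, automl)
      # pooled out-of-fold predictions at the selected mask/hyperparams
      oof_p <- rep(NA_real_, length(ytr)); oof_y <- ytr
      keep <- mask_columns(pp, fit$mask, fit$var_names)
      for (f in seq_len(plan$folds)) {
        tr_idx <- which(folds != f); va_idx <- which(folds == f)
        tr_sub <- cohort_subset(train, tr_idx)
        ppf <- fit_preprocess(tr_sub)
        keep_f <- mask_columns(ppf, fit$mask, fit$var_names)
        Xf <- apply_preprocess(ppf, tr_sub)[, keep_f, drop = FALSE]
        sm <- smote(Xf, ytr[tr_idx], k = automl$smote_k,
                    target_minority = automl$smote_target,
                    seed = derive_seed(seed, 500 + f))
        m <- fit_gbt(sm$X, sm$y, fit$hyperparams,
                     seed = derive_seed(seed, 600 + f))
        Xv <- apply_preprocess(ppf, cohort_subset(train, va_idx))[, keep_f, drop = FALSE]
        oof_p[va_idx] <- predict_gbt(m, Xv)
      }
      cv_eval <- if (paper_mode) {
        aug <- paper_mode_augment(Xtr[, keep, drop = FALSE], ytr, oof_p, fit,
                                  seed)
        eval_partition(aug$y, aug$p)
      } else {
        eval_partition(oof_y, oof_p)
      }
      te_p <- stats::predict(fit, test)
      te_eval <- if (paper_mode) {
        aug <- paper_mode_augment_table(fit, test, seed + 1)
        eval_partition(aug$y, aug$p)
      } else {
        eval_partition(yte, te_p)
      }
    } else {
      oof_p <- rep(NA_real_, length(ytr))
      for (f in seq_len(plan$folds)) {
        tr_idx <- which(folds != f); va_idx <- which(folds == f)
        ppf <- fit_preprocess(cohort_subset(train, tr_idx))
        Xf <- apply_preprocess(ppf, cohort_subset(train, tr_idx))
        sm <- smote(Xf, ytr[tr_idx], seed = derive_seed(seed, 700 + f))
        m <- train_model(spec, sm$X, sm$y, seed = derive_seed(seed, 800 + f))
        Xv <- apply_preprocess(ppf, cohort_subset(train, va_idx))
        oof_p[va_idx] <- predict_proba(m, Xv)
      }
      cv_eval <- eval_partition(ytr, oof_p)
      sm <- smote(Xtr, ytr, seed = derive_seed(seed, 900))
      m_full <- train_model(spec, sm$X, sm$y, seed = derive_seed(seed, 901))
      te_eval <- eval_partition(yte, predict_proba(m_full, Xte))
    }
    cv_rows[[spec$name]] <- as.data.frame(c(list(model = spec$name), cv_eval))
    te_rows[[spec$name]] <- as.data.frame(c(list(model = spec$name), te_eval))
  }
  list(cv = do.call(rbind, c(cv_rows, list(make.row.names = FALSE))),
       test = do.call(rbind, c(te_rows, list(make.row.names = FALSE))))
}

# paper_mode helpers: rebalance an evaluation partition with SMOTE and
# re-score the synthetic points with the fitted model
paper_mode_augment_table <- function(fit, table, seed) {
  keep <- mask_columns(fit$preprocess, fit$mask, fit$var_names)
  X <- apply_preprocess(fit$preprocess, table)[, keep, drop = FALSE]
  sm <- smote(X, table$outcome, seed = seed)
  list(y = sm$y, p = predict_gbt(fit$learner, sm$X))
}

paper_mode_augment <- function(X, y, p, fit, seed) {
  sm <- smote(X, y, seed = seed)
  new_rows <- which(sm$synthetic)
  p_new <- predict_gbt(fit$learner, sm$X[new_rows, , drop = FALSE])
  list(y = sm$y, p = c(p, p_new))
}
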