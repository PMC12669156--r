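#' Shapley-value feature attributions
#'
#' For gradient-boosted-tree models (an `automl_fit` or an xgboost
#' booster) the exact path-dependent tree algorithm is used (attributions
#' on the margin/log-odds scale, base value = the ensemble bias). For any
#' other model a permutation-sampling estimator is used: for every
#' background row and every antithetic permutation pair, features are
#' flipped one at a time from the background value to the explained value
#' and the output increments are credited to the flipped feature. Because
#' each permutation telescopes, local accuracy
#' `base_value + sum_j phi_ij = f(x_i)` holds exactly for the sampled
#' method and to numerical tolerance for the tree method.
#'
#' @param model an `automl_fit`, an `xgb.Booster`, a `fitted_model`, or a
#'   function mapping a feature matrix to a numeric output vector.
#' @param X_explain numeric matrix of samples to explain (for an
#'   `automl_fit`, a `cohort_table` is also accepted).
#' @param X_background background matrix (required for the sampling
#'   method; for tree models used only for the output summary).
#' @param nsamples number of antithetic permutation pairs (sampling
#'   method).
#' @param seed integer seed (sampling method).
#' @return object of class `shap_matrix`: `phi` (sample x feature),
#'   `base_value`, `output`, `method`, and `se` (sampling method only).
#' @export
shapley_values <- function(model, X_explain, X_background = NULL,
                           nsamples = 64L, seed = 1L) {
  if (inherits(model, "automl_fit")) {
    if (inherits(X_explain, "cohort_table")) {
      keep <- mask_columns(model$preprocess, model$mask, model$var_names)
      X_explain <- apply_preprocess(model$preprocess, X_explain)[, keep,
                                                                 drop = FALSE]
    }
    return(tree_shap(model$learner, X_explain))
  }
  if (inherits(model, "xgb.Booster")) {
    return(tree_shap(model, X_explain))
  }
  f <- if (inherits(model, "fitted_model")) {
    function(X) predict_proba(model, X)
  } else if (is.function(model)) {
    model
  } else {
    stop("unsupported model type for shapley_values", call. = FALSE)
  }
  if (is.null(X_background) || !nrow(X_background)) {
    stop("sampling Shapley needs a non-empty background", call. = FALSE)
  }
  if (nsamples < 2) stop("nsamples must be >= 2", call. = FALSE)
  sampling_shap(f, as.matrix(X_explain), as.matrix(X_background),
                nsamples, seed)
}

tree_shap <- function(booster, X) {
  X <- as.matrix(X)
  contrib <- stats::predict(booster, xgboost::xgb.DMatrix(X),
                            predcontrib = TRUE)
  contrib <- as.matrix(contrib)
  bias_col <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  if (!length(bias_col)) bias_col <- ncol(contrib)
  base <- contrib[1, bias_col]
  phi <- contrib[, -bias_col, drop = FALSE]
  colnames(phi) <- colnames(X)
  structure(list(phi = phi, base_value = unname(base),
                 output = unname(base + rowSums(phi)),
                 method = "tree", se = NULL),
            class = "shap_matrix")
}

sampling_shap <- function(f, X, B, npairs, seed) {
  d <- ncol(X); n <- nrow(X); nb <- nrow(B)
  cn <- colnames(X) %||% paste0("x", seq_len(d))
  base_value <- mean(f(B))
  phi <- matrix(0, n, d, dimnames = list(NULL, cn))
  se <- matrix(0, n, d, dimnames = list(NULL, cn))
  with_seed(seed, {
    perms <- replicate(npairs, sample(d), simplify = FALSE)
    for (i in seq_len(n)) {
      x <- X[i, ]
      # per-pair estimates for the Monte-Carlo standard error
      est <- array(0, c(npairs, d))
      for (r in seq_len(npairs)) {
        acc <- numeric(d)
        for (perm in list(perms[[r]], rev(perms[[r]]))) {
          # rows: background -> progressively overwritten with x along perm
          for (b in seq_len(nb)) {
            cur <- B[b, ]
            pts <- matrix(0, d + 1, d)
            pts[1, ] <- cur
            for (k in seq_len(d)) {
              cur[perm[k]] <- x[perm[k]]
              pts[k + 1, ] <- cur
            }
            colnames(pts) <- cn
            v <- f(pts)
            acc[perm] <- acc[perm] + diff(v)
          }
        }
        est[r, ] <- acc / (2 * nb)
      }
      phi[i, ] <- colMeans(est)
      se[i, ] <- apply(est, 2, stats::sd) / sqrt(npairs)
    }
  })
  structure(list(phi = phi, base_value = base_value,
                 output = unname(base_value + rowSums(phi)),
                 method = "sampling", se = se),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("shap_matrix (%s): %d samples x %d features, base value %.4f\n",
              x$method, nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' Global feature-importance ranking from Shapley values
#'
#' Ranks features by mean absolute attribution, descending, with ties
#' broken alphabetically. One-hot indicator columns can be aggregated back
#' to their source variable by passing the column-to-variable map, in
#' which case per-sample contributions are summed within each variable
#' before taking the mean absolute value.
#'
#' @param shap a `shap_matrix`.
#' @param column_var optional character vector mapping each phi column to
#'   a source variable name (e.g. `preprocess$column_var`).
#' @return data.frame with `feature`, `importance` (mean |phi|), sorted.
#' @export
shap_importance <- function(shap, column_var = NULL) {
  phi <- shap$phi
  if (!is.null(column_var)) {
    stopifnot(length(column_var) == ncol(phi))
    vars <- unique(column_var)
    agg <- vapply(vars, function(v) {
      rowSums(phi[, column_var == v, drop = FALSE])
    }, numeric(nrow(phi)))
    phi <- matrix(agg, nrow(shap$phi), length(vars),
                  dimnames = list(NULL, vars))
  }
  imp <- colMeans(abs(phi))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]))
}

#' Threshold-interaction summary for a feature pair
#'
#' Splits the explained samples into the four quadrants defined by two
#' feature thresholds (e.g. CRP > 10 mg/L crossed with D-dimer >
#' 1.5 mg/L), averages the pair's joint Shapley contribution in each
#' quadrant and reports the synergy excess
#' `m_HH - m_HL - m_LH + m_LL` — zero in expectation for a purely additive
#' model, positive when the joint elevation carries risk beyond the sum of
#' the single elevations.
#'
#' @param shap a `shap_matrix` whose columns include the pair (aggregate
#'   one-hot columns first via `column_var` handling if needed).
#' @param values data.frame/list with the raw (unstandardised) values of
#'   the two features for every explained sample.
#' @param pair character vector of the two feature names.
#' @param thresholds numeric thresholds, same order as `pair`.
#' @return object of class `interaction_summary`: quadrant table (mean
#'   joint contribution, count), `synergy`, `synergy_se`, `flagged`.
#' @export
interaction_summary <- function(shap, values, pair, thresholds) {
  stopifnot(length(pair) == 2, length(thresholds) == 2)
  phi <- shap$phi
  if (!all(pair %in% colnames(phi))) {
    stop("pair features missing from shap matrix: ",
         paste(setdiff(pair, colnames(phi)), collapse = ", "), call. = FALSE)
  }
  s <- phi[, pair[1]] + phi[, pair[2]]
  hi1 <- values[[pair[1]]] > thresholds[1]
  hi2 <- values[[pair[2]]] > thresholds[2]
  quad <- factor(paste0(ifelse(hi1, "H", "L"), ifelse(hi2, "H", "L")),
                 levels = c("HH", "HL", "LH", "LL"))
  tab <- data.frame(
    quadrant = levels(quad),
    mean_contribution = vapply(levels(quad), function(q) {
      if (any(quad == q)) mean(s[quad == q]) else NA_real_
    }, numeric(1)),
    count = as.integer(table(quad))
  )
  m <- stats::setNames(tab$mean_contribution, tab$quadrant)
  v <- vapply(levels(quad), function(q) {
    k <- sum(quad == q)
    if (k > 1) stats::var(s[quad == q]) / k else NA_real_
  }, numeric(1))
  synergy <- m[["HH"]] - m[["HL"]] - m[["LH"]] + m[["LL"]]
  synergy_se <- sqrt(sum(v))
  structure(list(pair = pair, thresholds = thresholds, quadrants = tab,
                 synergy = unname(synergy), synergy_se = unname(synergy_se),
                 flagged = isTRUE(abs(synergy) > 2 * synergy_se)),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("interaction_summary: %s x %s (thresholds %g, %g)\n",
              x$pair[1], x$pair[2], x$thresholds[1], x$thresholds[2]))
  print(x$quadrants, digits = 4)
  cat(sprintf("synergy %.4f (SE %.4f)%s\n", x$synergy, x$synergy_se,
              if (x$flagged) " *" else ""))
  invisible(x)
}
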