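#' L1-penalised logistic regression path with cross-validated selection
#'
#' Warm-started coordinate-descent fit (glmnet backend, convergence
#' threshold 1e-11) of the penalised objective
#' `-(1/n) loglik + lambda * sum(|beta_j|)` (intercept unpenalised) along a
#' log-spaced lambda grid, with k-fold cross-validated binomial deviance on
#' stratified folds. `lambda_1se` is the largest lambda whose CV deviance
#' is within one standard error of the minimum — the sparsity-favouring
#' selection rule; the features with nonzero coefficients there form the
#' selected set. The backend truncates the grid where the fit saturates
#' (its standard deviance-progress rule), so the returned grid can be
#' shorter than requested.
#'
#' @param X standardized numeric feature matrix (named columns).
#' @param y binary outcome vector.
#' @param lambdas optional decreasing lambda grid; by default `nlambda`
#'   points spanning a `lambda_ratio` range below the smallest all-zero
#'   lambda.
#' @param nlambda,lambda_ratio grid size and span when `lambdas` is `NULL`.
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return object of class `lasso_path`: `lambda`, `beta` (feature x
#'   lambda), `intercept`, `cv_mean`, `cv_se`, `lambda_min`, `lambda_1se`,
#'   `selected`, `nonzero`.
#' @export
lasso_logistic_path <- function(X, y, lambdas = NULL, nlambda = 100L,
                                lambda_ratio = 1e-4, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  args <- list(x = X, y = y, family = "binomial", standardize = FALSE,
               thresh = 1e-11, maxit = 1e6)
  if (is.null(lambdas)) {
    args$nlambda <- nlambda
    args$lambda.min.ratio <- lambda_ratio
  } else {
    args$lambda <- sort(lambdas, decreasing = TRUE)
  }
  fit <- do.call(glmnet::glmnet, args)
  lambda <- fit$lambda
  plan <- cv_plan(folds, seed)
  foldid <- make_folds(as.integer(y), plan)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", standardize = FALSE,
                          thresh = 1e-11, maxit = 1e6, lambda = lambda,
                          foldid = foldid, type.measure = "deviance")
  # align the CV curve to the master grid (cv.glmnet may drop tail points)
  idx <- match(round(cv$lambda, 12), round(lambda, 12))
  cv_mean <- rep(NA_real_, length(lambda)); cv_se <- cv_mean
  cv_mean[idx] <- cv$cvm
  cv_se[idx] <- cv$cvsd
  i_min <- which(lambda == cv$lambda.min)[1]
  i_1se <- which(lambda == cv$lambda.1se)[1]
  beta <- as.matrix(fit$beta)
  sel <- rownames(beta)[abs(beta[, i_1se]) > 0]
  structure(list(lambda = lambda, beta = beta,
                 intercept = as.numeric(fit$a0),
                 cv_mean = cv_mean, cv_se = cv_se,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 selected = sel,
                 nonzero = colSums(abs(beta) > 0)),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "lasso_path: %d lambdas, lambda_min %.4g, lambda_1se %.4g, %d selected\n",
    length(x$lambda), x$lambda_min, x$lambda_1se, length(x$selected)))
  invisible(x)
}

#' KKT subgradient residuals of a lasso solution
#'
#' Independent optimality oracle. For each lambda, returns the maximum
#' violation of the stationarity conditions: `|g_j| <= lambda` for zero
#' coefficients and `g_j = lambda * sign(beta_j)` for active ones, where
#' `g_j = (1/n) X_j'(y - p)` is the unpenalised score.
#'
#' @param path a `lasso_path`.
#' @param X,y the data the path was fitted on.
#' @return numeric vector of max violations per lambda.
#' @export
lasso_kkt_violation <- function(path, X, y) {
  X <- as.matrix(X); n <- nrow(X)
  vapply(seq_along(path$lambda), function(l) {
    beta <- path$beta[, l]
    eta <- drop(X %*% beta) + path$intercept[l]
    g <- drop(crossprod(X, y - 1 / (1 + exp(-eta)))) / n
    lam <- path$lambda[l]
    zero <- beta == 0
    v1 <- if (any(zero)) max(pmax(abs(g[zero]) - lam, 0)) else 0
    v2 <- if (any(!zero)) max(abs(g[!zero] - lam * sign(beta[!zero]))) else 0
    max(v1, v2)
  }, numeric(1))
}

#' Overlap between a reference and a candidate feature set
#'
#' Fraction of the reference set recovered by the candidate:
#' `|reference intersect candidate| / |reference|`.
#'
#' @param reference non-empty character vector (denominator set).
#' @param candidate character vector.
#' @return list with `fraction` (0..1) and `intersection`.
#' @export
feature_overlap <- function(reference, candidate) {
  reference <- unique(reference)
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  inter <- intersect(reference, candidate)
  list(fraction = length(inter) / length(reference), intersection = inter)
}
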