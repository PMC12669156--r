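#' SMOTE: synthetic minority oversampling
#'
#' Grows the minority class to `target_minority` rows by interpolating
#' between each sampled minority point and one of its `k` nearest minority
#' neighbours (Euclidean distance in feature space):
#' `x_new = x_i + u * (x_nn - x_i)` with `u ~ U(0, 1)`. Original rows are
#' always retained; with `target_minority` at the current count the data
#' pass through untouched.
#'
#' @param X numeric feature matrix.
#' @param y binary vector (1 = minority assumed the rarer class).
#' @param k number of nearest minority neighbours (default 5).
#' @param target_minority desired minority count after augmentation;
#'   default near-parity with the majority class.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with augmented `X`, `y`, and `synthetic` (logical flag per
#'   row).
#' @export
smote <- function(X, y, k = 5L, target_minority = NULL, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (is.null(target_minority)) target_minority <- max(counts)
  n_new <- target_minority - n_min
  if (n_new <= 0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  if (n_min <= k) {
    stop("minority count (", n_min, ") must exceed k = ", k,
         "; use a smaller k", call. = FALSE)
  }
  gen <- function() {
    M <- X[min_idx, , drop = FALSE]
    # pairwise distances among minority points
    d2 <- as.matrix(stats::dist(M))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    parent <- sample(n_min, n_new, replace = TRUE)
    nbr <- nn[cbind(parent, sample(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    Xs <- M[parent, , drop = FALSE] +
      u * (M[nbr, , drop = FALSE] - M[parent, , drop = FALSE])
    list(X = rbind(X, Xs),
         y = c(y, rep(minority, n_new)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
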