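#' Stratified train/test split
#'
#' Partitions a cohort into training and testing sets, stratified on the
#' binary outcome. The overall training size is `round(train_fraction * N)`;
#' per-stratum allocations are rounded by the largest-remainder rule so they
#' sum exactly to that total, with remainder ties broken in favour of the
#' minority class. An 826-record cohort with 128 events at fraction 0.8
#' therefore yields a 661-record training set with 103 events.
#'
#' @param table a `cohort_table`.
#' @param train_fraction fraction of records assigned to training (0, 1).
#' @param seed integer seed making membership reproducible.
#' @return object of class `split_result` with `train_index`, `test_index`,
#'   `ratio`, `seed`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- table$outcome
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present to stratify", call. = FALSE)
  }
  n <- length(y)
  n_train <- round(train_fraction * n)
  strata <- list(pos = which(y == 1L), neg = which(y == 0L))
  exact <- vapply(strata, length, integer(1)) * train_fraction
  base <- floor(exact)
  remainder <- exact - base
  short <- n_train - sum(base)
  take <- base
  if (short > 0) {
    # largest remainder first; ties go to the minority class
    minority <- if (length(strata$pos) <= length(strata$neg)) "pos" else "neg"
    ord <- order(-remainder, names(strata) != minority)
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
  }
  train_index <- integer(0)
  with_seed(seed, {
    for (s in names(strata)) {
      idx <- strata[[s]]
      train_index <- c(train_index, sort(sample(idx, take[[s]])))
    }
  })
  train_index <- sort(train_index)
  structure(list(train_index = train_index,
                 test_index = setdiff(seq_len(n), train_index),
                 ratio = train_fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_index), length(x$test_index), x$ratio, x$seed))
  invisible(x)
}
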