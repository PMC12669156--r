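# exact Shapley values by subset enumeration, with the value of a coalition
# S defined as the background-expectation of f with the complement drawn
# from the background rows — the same game the sampling estimator plays
exact_shapley <- function(f, x, B) {
  d <- length(x)
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  vals <- apply(subsets, 1, function(S) {
    Xs <- B
    Xs[, S] <- matrix(x[S], nrow(B), sum(S), byrow = TRUE)
    mean(f(Xs))
  })
  key <- function(S) sum(2^(which(S) - 1)) + 1
  for (j in seq_len(d)) {
    for (r in seq_len(nrow(subsets))) {
      S <- unlist(subsets[r, ])
      if (S[j]) next
      s <- sum(S)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      Sj <- S
      Sj[j] <- TRUE
      phi[j] <- phi[j] + w * (vals[key(Sj)] - vals[key(S)])
    }
  }
  phi
}
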