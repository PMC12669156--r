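test_that("sampling Shapley recovers the closed form of a linear game", {
  set.seed(5)
  d <- 5
  w <- c(2, -1, 0.5, 0, 1.5)
  f <- function(X) as.numeric(as.matrix(X) %*% w)
  B <- matrix(rnorm(15 * d), 15, d)
  Xe <- matrix(rnorm(4 * d), 4, d)
  sh <- shapley_values(f, Xe, B, nsamples = 6, seed = 2)
  closed <- sweep(Xe, 2, colMeans(B)) %*% diag(w)
  expect_lt(max(abs(sh$phi - closed)), 1e-6)
  # local accuracy per explained sample
  expect_lt(max(abs(sh$base_value + rowSums(sh$phi) - f(Xe))), 1e-10)
  expect_error(shapley_values(f, Xe, B, nsamples = 1), "nsamples")
  expect_error(shapley_values(f, Xe, NULL), "background")
})

test_that("sampling Shapley matches exhaustive enumeration on a d=8 toy", {
  set.seed(9)
  d <- 8
  f <- function(X) {
    X <- as.matrix(X)
    X[, 1] * X[, 2] + sin(X[, 3]) + 0.5 * X[, 4]^2 - X[, 5] + 0.2 * X[, 6]
  }
  B <- matrix(rnorm(8 * d), 8, d)
  x <- rnorm(d)
  sh <- shapley_values(f, matrix(x, 1), B, nsamples = 60, seed = 4)
  phi_exact <- exact_shapley(f, x, B)
  # agreement within three Monte-Carlo standard errors (floor for the
  # features the game ignores, whose SE is numerically zero)
  tol <- pmax(3 * sh$se[1, ], 1e-9)
  expect_true(all(abs(sh$phi[1, ] - phi_exact) <= tol))
  expect_equal(sh$base_value + sum(sh$phi[1, ]), f(matrix(x, 1)),
               tolerance = 1e-10)
})

test_that("duplicated features earn symmetric attributions", {
  set.seed(11)
  n <- 150
  z <- rnorm(n)
  X <- cbind(a = z, b = z, c = rnorm(n))
  f <- function(M) as.matrix(M)[, "a"] + as.matrix(M)[, "b"]
  sh <- shapley_values(f, X[1:25, ], X, nsamples = 40, seed = 3)
  imp <- colMeans(abs(sh$phi))
  expect_equal(unname(imp["a"]), unname(imp["b"]),
               tolerance = 0.1 * max(imp))
})

test_that("tree SHAP satisfies local accuracy against the margin output", {
  co <- toy_signal_cohort(250, 4, seed = 3)
  pp <- fit_preprocess(co)
  X <- apply_preprocess(pp, co)
  hp <- list(nrounds = 50L, max_depth = 3L, eta = 0.2, subsample = 1,
             min_child_weight = 2, lambda = 1)
  booster <- stentrisk:::fit_gbt(X, co$outcome, hp, seed = 2)
  sh <- shapley_values(booster, X[1:40, ])
  margin <- predict(booster, xgboost::xgb.DMatrix(X[1:40, ]),
                    outputmargin = TRUE)
  expect_lt(max(abs(sh$base_value + rowSums(sh$phi) - margin)), 1e-4)
  expect_equal(sh$method, "tree")
})

test_that("importance ranks by mean |phi|, aggregates one-hots, ignores order", {
  set.seed(13)
  phi <- cbind(big = rnorm(50, 0, 2), small = rnorm(50, 0, 0.1),
               `cat=a` = rnorm(50, 0, 0.5), `cat=b` = rnorm(50, 0, 0.5))
  sh <- structure(list(phi = phi, base_value = 0, method = "tree"),
                  class = "shap_matrix")
  imp <- shap_importance(sh)
  expect_equal(imp$feature[1], "big")
  sh2 <- sh
  sh2$phi <- phi[sample(50), ]
  expect_equal(shap_importance(sh2)$importance, imp$importance,
               tolerance = 1e-12)
  agg <- shap_importance(sh, column_var = c("big", "small", "cat", "cat"))
  expect_equal(nrow(agg), 3)
  expect_true("cat" %in% agg$feature)
  # a model using a single feature puts it first with the rest near zero
  f1 <- function(M) 3 * as.matrix(M)[, 2]
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("u", "v", "w")))
  s1 <- shapley_values(f1, X[1:10, ], X, nsamples = 10, seed = 5)
  i1 <- shap_importance(s1)
  expect_equal(i1$feature[1], "v")
  expect_lt(max(i1$importance[-1]), 1e-10)
})

test_that("an additive model shows no threshold synergy", {
  set.seed(15)
  n <- 400
  X <- cbind(crp = rlnorm(n, log(9), 0.6), dd = rlnorm(n, log(1.3), 0.6))
  f <- function(M) {
    M <- as.matrix(M)
    0.4 * log(M[, "crp"]) + 0.7 * log(M[, "dd"])
  }
  sh <- shapley_values(f, X, X[1:40, ], nsamples = 4, seed = 6)
  isum <- interaction_summary(sh, as.data.frame(X), c("crp", "dd"),
                              c(10, 1.5))
  expect_equal(sum(isum$quadrants$count), n)
  expect_lt(abs(isum$synergy), 2.5 * isum$synergy_se)
})
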