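sphere <- function(x) sum(x^2)

test_that("logistic chaos map iterates exactly and rejects degenerate orbits", {
  expect_equal(logistic_chaos_sequence(0.7, 2), c(0.84, 0.5376))
  expect_error(logistic_chaos_sequence(0.75, 5), "degenerate")
  expect_error(logistic_chaos_sequence(0, 5), "degenerate")
  s <- logistic_chaos_sequence(0.31, 1e5)
  expect_true(all(s > 0 & s < 1))
  # invariant density is arcsine: empirical CDF close to Beta(1/2, 1/2)
  d_stat <- max(abs(sort(s) - qbeta(ppoints(1e5), 0.5, 0.5)))
  expect_lt(d_stat, 0.02)
})

test_that("population initialisation is bounded, seeded and chaos spreads wider", {
  space <- search_space(c(0, -2), c(1, 2))
  cfg <- optimizer_config(pop_size = 30, max_iters = 10, seed = 5)
  P1 <- init_population(space, cfg)
  expect_true(all(P1[, 1] >= 0 & P1[, 1] <= 1))
  expect_true(all(P1[, 2] >= -2 & P1[, 2] <= 2))
  expect_identical(P1, init_population(space, cfg))
  # chaotic minimum pairwise distance beats uniform in most seeded trials
  sp2 <- search_space(c(0, 0), c(1, 1))
  wins <- 0L
  for (s in 1:50) {
    c_ch <- optimizer_config(pop_size = 400, max_iters = 1, seed = s,
                             chaotic_init = TRUE)
    c_un <- optimizer_config(pop_size = 400, max_iters = 1, seed = s,
                             chaotic_init = FALSE)
    d_ch <- min(dist(init_population(sp2, c_ch)))
    d_un <- min(dist(init_population(sp2, c_un)))
    wins <- wins + (d_ch >= d_un)
  }
  expect_gte(wins, 30)
})

test_that("Mantegna sigma and Levy steps have the stable-law signatures", {
  # closed form with Gamma(2.5) = 1.32934, Gamma(1.25) = 0.90640
  expect_equal(levy_sigma(1.5), 0.696575, tolerance = 1e-5)
  expect_error(mantegna_levy(2.5, 10, 1), "beta")
  expect_error(mantegna_levy(1, 10, 1))
  s <- mantegna_levy(1.5, 1e5, seed = 2)
  expect_identical(s, mantegna_levy(1.5, 1e5, seed = 2))
  expect_true(is.finite(median(abs(s))))
  # power-law tail: the extreme-to-bulk quantile ratio far exceeds the
  # Gaussian value (~2.4 for these probabilities)
  q <- quantile(abs(s), c(0.9, 0.999))
  expect_gt(q[[2]] / q[[1]], 8)
})

test_that("the step-scale schedule decays exponentially", {
  expect_equal(step_scale(0, 100, 0.5), 0.5)
  expect_equal(step_scale(100, 100, 0.5), 0.5 * exp(-4))
  grid <- sapply(0:50, step_scale, T = 50, alpha0 = 1)
  expect_true(all(diff(grid) < 0))
})

test_that("ISequoiaOA converges on the sphere with a monotone history", {
  space <- search_space(rep(-5, 2), rep(5, 2))
  res <- iseq_optimize(sphere, space, optimizer_config(30, 200, seed = 3))
  expect_lt(res$best_fitness, 1e-6)
  expect_length(res$history, 200)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$best_fitness, res$history[200])
  expect_true(all(res$best_position >= -5 & res$best_position <= 5))
  res2 <- iseq_optimize(sphere, space, optimizer_config(30, 200, seed = 3))
  expect_identical(res, res2)
})

test_that("non-finite objective values are discarded with a warning, not fatal", {
  space <- search_space(rep(-5, 2), rep(5, 2))
  spiky <- function(x) if (x[1] > 4) NaN else sphere(x)
  w <- testthat::capture_warnings(
    iseq_optimize(spiky, space, optimizer_config(10, 1, seed = 2)))
  expect_true(any(grepl("non-finite", w)))
  res <- suppressWarnings(
    iseq_optimize(spiky, space, optimizer_config(10, 30, seed = 2)))
  expect_true(is.finite(res$best_fitness))
  expect_lt(res$best_fitness, 1)  # the run continued and still optimized
})

test_that("every baseline algorithm solves small separable problems", {
  space2 <- search_space(rep(-5, 2), rep(5, 2))
  ellipsoid <- function(x) sum(10^(3 * (seq_along(x) - 1) / 2) * x^2)
  space3 <- search_space(rep(-5, 3), rep(5, 3))
  for (alg in c("PSO", "GA", "GWO", "WOA", "SequoiaOA", "ISequoiaOA")) {
    r <- baseline_optimize(alg, sphere, space2, optimizer_config(30, 200, seed = 3))
    expect_lt(r$best_fitness, 1e-3)
    expect_true(all(diff(r$history) <= 0))
    r2 <- baseline_optimize(alg, sphere, space2, optimizer_config(30, 200, seed = 3))
    expect_identical(r$history, r2$history)
    re <- baseline_optimize(alg, ellipsoid, space3,
                            optimizer_config(30, 250, seed = 6))
    expect_lt(re$best_fitness, 1e-3)
  }
})

test_that("ISequoiaOA beats random search on a multimodal landscape", {
  d <- 5
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  space <- search_space(rep(-5.12, d), rep(5.12, d))
  pop <- 30; iters <- 60; runs <- 8
  iseq_final <- sapply(seq_len(runs), function(r) {
    iseq_optimize(rastrigin, space,
                  optimizer_config(pop, iters, seed = 100 + r))$best_fitness
  })
  rand_final <- sapply(seq_len(runs), function(r) {
    set.seed(200 + r)
    X <- matrix(runif(pop * (iters + 1) * d, -5.12, 5.12), ncol = d)
    min(apply(X, 1, rastrigin))
  })
  expect_lt(median(iseq_final), median(rand_final))
})
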