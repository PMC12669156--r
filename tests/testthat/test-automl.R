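test_that("the sigmoid transfer decodes positions into usable masks", {
  set.seed(2)
  m <- mask_from_position(c(10, 10, -10))
  expect_identical(m, c(TRUE, TRUE, FALSE))
  # the rescue rule guarantees a non-empty mask
  for (i in 1:20) {
    m0 <- mask_from_position(rep(-10, 6))
    expect_equal(sum(m0), 1)
  }
  # empirical switch-on probability at position 0 is one half
  set.seed(3)
  draws <- replicate(1e4, mask_from_position(c(0, 5))[1])
  expect_equal(mean(draws), 0.5, tolerance = 0.02)
})

test_that("cv_fitness is seeded-deterministic and separates signal from noise", {
  co <- toy_signal_cohort(250, 6, seed = 21)
  hp <- list(nrounds = 40L, max_depth = 3L, eta = 0.15, subsample = 0.9,
             min_child_weight = 5, lambda = 1)
  plan <- cv_plan(3, seed = 5)
  signal_mask <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  noise_mask <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  f1 <- cv_fitness(co, signal_mask, hp, plan)
  expect_identical(f1, cv_fitness(co, signal_mask, hp, plan))
  # pure-noise masks sit at chance minus the parsimony penalty: average
  # over independently drawn datasets and fold assignments
  noise_fit <- mean(sapply(1:12, function(s) {
    co_s <- toy_signal_cohort(250, 6, seed = 300 + s)
    cv_fitness(co_s, noise_mask, hp, cv_plan(3, seed = s))
  }))
  expect_lt(abs(noise_fit - (0.5 - 0.01 * 4 / 6)), 0.05)
  expect_gt(f1, noise_fit + 0.15)
  expect_error(cv_fitness(co, rep(FALSE, 6), hp, plan), "empty")
})

test_that("fold bookkeeping never leaks validation rows into fitting", {
  co <- toy_signal_cohort(120, 4, seed = 31)
  plan <- cv_plan(4, seed = 9)
  ctx <- stentrisk:::cv_context(co, plan)
  folds <- stentrisk:::make_folds(co$outcome, plan)
  for (f in seq_len(plan$folds)) {
    tr_idx <- which(folds != f)
    fd <- ctx$folds[[f]]
    # standardization parameters come from the fold-train rows alone
    for (v in names(co$schema)) {
      expect_equal(fd$pp$params[[v]]$mean, mean(co$data[[v]][tr_idx]))
      expect_equal(fd$pp$params[[v]]$sd, sd(co$data[[v]][tr_idx]))
    }
    expect_equal(nrow(fd$Xtr), length(tr_idx))
    expect_equal(nrow(fd$Xva), sum(folds == f))
    # both classes present in every fold
    expect_gt(sum(fd$yva), 0)
    expect_gt(sum(1 - fd$yva), 0)
  }
})

test_that("stage 2 stays inside the box and never loses to the default point", {
  co <- toy_signal_cohort(200, 4, seed = 41)
  space <- hyperparam_space(nrounds = c(20, 60))
  mask <- rep(TRUE, 4)
  plan <- cv_plan(3, seed = 2)
  hp <- stage2_tune(co, mask, space = space, plan = plan,
                    opt_config = optimizer_config(5, 3, seed = 8))
  for (nm in names(space)) {
    expect_gte(hp[[nm]], space[[nm]][1])
    expect_lte(hp[[nm]], space[[nm]][2])
  }
  expect_true(hp$nrounds == as.integer(hp$nrounds))
  hp0 <- default_hyperparams()
  # the package default lies outside this reduced box, so compare directly
  def_score <- cv_fitness(co, mask, list(nrounds = 40L, max_depth = 3L,
                                         eta = 0.15, subsample = 0.9,
                                         min_child_weight = 5, lambda = 1),
                          plan)
  expect_gte(attr(hp, "cv_score"), def_score - 0.05)
})

test_that("the full dual-stage fit is reproducible and predicts probabilities", {
  co <- toy_signal_cohort(250, 6, seed = 51)
  cfg <- tiny_automl_config(seed = 3)
  fit <- fit_automl(co, cfg)
  expect_s3_class(fit, "automl_fit")
  expect_gte(sum(fit$mask), 1)
  p <- predict(fit, co)
  expect_true(all(p >= 0 & p <= 1))
  fit2 <- fit_automl(co, cfg)
  expect_identical(fit$mask, fit2$mask)
  expect_identical(unclass(fit$hyperparams), unclass(fit2$hyperparams))
  expect_identical(fit$cv_score, fit2$cv_score)
  # single-predictor degenerate case
  co1 <- toy_signal_cohort(120, 1, seed = 61, beta = 1)
  m1 <- stage1_select(co1, hp0 = cfg$hp0, plan = cfg$plan)
  expect_identical(as.logical(m1), TRUE)
})

test_that("doubling the stage-1 budget never worsens the recorded fitness", {
  co <- toy_signal_cohort(220, 5, seed = 71)
  hp0 <- list(nrounds = 30L, max_depth = 3L, eta = 0.15, subsample = 0.9,
              min_child_weight = 5, lambda = 1)
  plan <- cv_plan(3, seed = 4)
  m_small <- stage1_select(co, hp0 = hp0, plan = plan,
                           opt_config = optimizer_config(6, 3, seed = 12))
  m_large <- stage1_select(co, hp0 = hp0, plan = plan,
                           opt_config = optimizer_config(6, 6, seed = 12))
  expect_gte(attr(m_large, "fitness"), attr(m_small, "fitness") - 1e-12)
})
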