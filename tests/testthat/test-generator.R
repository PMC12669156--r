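test_that("the shifted log-normal matcher reproduces printed quantiles", {
  fit <- match_lognormal(1.25, 0.78, 1.96)
  q <- fit$gamma + qlnorm(c(0.25, 0.5, 0.75), fit$mu, fit$sigma)
  expect_equal(q, c(0.78, 1.25, 1.96), tolerance = 1e-6)
  fit2 <- match_lognormal(8.6, 4.2, 14.3)
  q2 <- fit2$gamma + qlnorm(c(0.25, 0.5, 0.75), fit2$mu, fit2$sigma)
  expect_equal(q2, c(4.2, 8.6, 14.3), tolerance = 1e-6)
  # symmetric quartiles admit no right-skewed log-normal
  expect_null(match_lognormal(25.8, 23.1, 28.5))
})

test_that("the default spec encodes the published marginals and validates", {
  spec <- the_spec()
  expect_length(spec$variables, 22)
  etio <- spec$variables$etiology
  expect_equal(etio$probs,
               c(0.3253, 0.2693, 0.1543, 0.1831, 0.0681) /
                 sum(c(0.3253, 0.2693, 0.1543, 0.1831, 0.0681)))
  expect_equal(sum(etio$probs), 1)
  expect_equal(sum(spec$variables$anticoagulation$probs), 1)
  expect_equal(spec$variables$age$mean, 58.92)
  expect_equal(spec$variables$eiv_recan$upper, 100)
  expect_true(is.finite(spec$intercept))
  # the recanalization interaction was solved to a positive coefficient
  recan <- Filter(function(tm) {
    tm$type == "threshold_interaction" && identical(tm$var1, "cfv_recan")
  }, spec$terms)[[1]]
  expect_gt(recan$coef, 0)
})

test_that("sampling is seeded, bounded and recovers the marginal shapes", {
  spec <- the_spec()
  co <- sample_cohort(spec, 826, seed = 20250826)
  expect_identical(co$data, sample_cohort(spec, 826, seed = 20250826)$data)
  expect_true(all(co$data$eiv_recan >= 0 & co$data$eiv_recan <= 100))
  expect_true(all(co$data$cfv_recan >= 0 & co$data$cfv_recan <= 100))
  # mean age within 3 standard errors of the target
  expect_lt(abs(mean(co$data$age) - 58.92), 3 * 12.43 / sqrt(826) + 0.3)
  big <- sample_cohort(spec, 20000, seed = 4)
  q <- quantile(big$data$d_dimer, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), c(0.78, 1.25, 1.96), tolerance = 0.06)
  expect_equal(mean(big$data$sex_male), 0.5991, tolerance = 0.02)
  tab <- table(big$data$etiology) / 20000
  expect_equal(unname(as.vector(tab)), unname(spec$variables$etiology$probs),
               tolerance = 0.02)
})

test_that("cohort prevalence concentrates on the calibration target", {
  spec <- the_spec()
  prev <- sapply(1:30, function(s) mean(sample_cohort(spec, 826, s)$outcome))
  se <- sqrt(0.155 * 0.845 / (30 * 826))
  expect_lt(abs(mean(prev) - 0.155), 2 * se + 0.002)
})

test_that("the outcome model is monotone in the recanalization risk factors", {
  spec <- the_spec()
  rec <- stentrisk:::typical_record(spec)
  lo <- rec; lo$cfv_recan <- 60; lo$eiv_recan <- 60
  hi <- rec; hi$cfv_recan <- 80; hi$eiv_recan <- 80
  expect_gt(outcome_probability(lo, spec), outcome_probability(hi, spec))
  # dual insufficiency doubles the risk at the typical covariate point
  mid <- rec; mid$cfv_recan <- 65; mid$eiv_recan <- 65
  spec0 <- spec
  idx <- which(sapply(spec0$terms, function(tm) {
    tm$type == "threshold_interaction" && identical(tm$var1, "cfv_recan")
  }))
  spec0$terms[[idx]]$coef <- 0
  expect_equal(outcome_probability(mid, spec) / outcome_probability(mid, spec0),
               2, tolerance = 1e-6)
})

test_that("intercept calibration has its closed-form and idempotence properties", {
  spec <- the_spec()
  # no effects: the intercept is exactly the logit of the target
  null_spec <- spec
  null_spec$terms <- list()
  b0 <- calibrate_intercept(null_spec, 0.155)
  expect_equal(b0, qlogis(0.155), tolerance = 1e-6)
  # recalibrating the calibrated spec reproduces the stored intercept
  b1 <- calibrate_intercept(spec, spec$target_prevalence)
  expect_equal(b1, spec$intercept, tolerance = 1e-6)
  # Monte-Carlo prevalence at the stored intercept sits inside the band
  big <- sample_cohort(spec, 50000, seed = 77)
  expect_equal(mean(big$outcome), 0.155, tolerance = 0.006)
  expect_error(calibrate_intercept(null_spec, 1.5), "target")
})

test_that("a zero-variance variable yields a constant column", {
  spec <- the_spec()
  spec$variables$age <- list(dist = "normal", mean = 60, sd = 0)
  co <- sample_cohort(spec, 50, seed = 2)
  expect_equal(unique(co$data$age), 60)
})

test_that("generator specs survive a JSON round trip", {
  spec <- the_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_spec(spec, path)
  back <- read_generator_spec(path)
  expect_equal(back$intercept, spec$intercept)
  expect_equal(length(back$terms), length(spec$terms))
  rec <- stentrisk:::typical_record(spec)
  expect_equal(outcome_probability(rec, back), outcome_probability(rec, spec),
               tolerance = 1e-12)
  co1 <- sample_cohort(spec, 40, seed = 6)
  co2 <- sample_cohort(back, 40, seed = 6)
  expect_equal(co1$data, co2$data)
})
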