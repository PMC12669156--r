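test_that("pooled t from summaries agrees with the raw-data pooled t test", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ours <- pooled_t_from_summary(n1, mean(x), sd(x), n2, mean(y), sd(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_lt(abs(ours$statistic - abs(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-10)
  }
})

test_that("pooled t degenerate cases follow the zero-variance conventions", {
  r <- pooled_t_from_summary(10, 5, 2, 10, 5, 2)
  expect_equal(r$statistic, 0)
  r <- pooled_t_from_summary(10, 5, 0, 10, 5, 0)
  expect_equal(r, list(statistic = 0, p_value = 1))
  expect_error(pooled_t_from_summary(10, 5, 0, 10, 6, 0), "infinite")
})

test_that("Pearson chi-square matches brute force and chisq.test without correction", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(2 * k, 30) + 1, 2, k)
    ours <- pearson_chi2(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(ours$statistic, sum((tab - expected)^2 / expected))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(pearson_chi2(prop)$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "zero margin")
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  same <- c(1, 2, 2, 3, 5, 5)
  expect_gt(mann_whitney_u(same, same)$p_value, 0.95)
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:15, 20, replace = TRUE)
    y <- sample(1:15, 20, replace = TRUE)
    u_brute_x <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    u_brute <- min(u_brute_x, length(x) * length(y) - u_brute_x)
    expect_equal(mann_whitney_u(x, y)$statistic, u_brute)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(mann_whitney_u(x, y)$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("baseline table dispatches by kind and shows balanced partitions", {
  co <- the_cohort(826, seed = 20250826)
  sp <- stratified_split(co, 0.8, seed = 4)
  bt <- baseline_table(co, sp)
  expect_equal(nrow(bt), 23)  # outcome + 22 predictors
  expect_true(all(bt$p_value >= 0 & bt$p_value <= 1))
  expect_equal(bt$test[bt$variable == "etiology"], "pearson_chi2")
  expect_equal(bt$test[bt$variable == "occlusion"], "pearson_chi2")
  # skewed biomarkers should fail the normality gate
  expect_equal(bt$test[bt$variable == "d_dimer"], "mann_whitney_u")
  # a stratified random split leaves nearly all variables balanced
  expect_gte(sum(bt$p_value > 0.05), 20)
})

test_that("a constant variable yields statistic 0 and p 1", {
  co <- the_cohort(100, seed = 8)
  co$data$age <- rep(50, 100)
  sp <- stratified_split(co, 0.8, seed = 2)
  bt <- baseline_table(co, sp)
  expect_equal(bt$statistic[bt$variable == "age"], 0)
  expect_equal(bt$p_value[bt$variable == "age"], 1)
})
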