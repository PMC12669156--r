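test_that("confusion counts match a brute-force loop on random instances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.4)
    p <- runif(n)
    thr <- runif(1, 0.1, 0.9)
    cc <- confusion(y, p, thr)
    tp <- fp <- tn <- fn <- 0
    for (j in seq_len(n)) {
      if (p[j] >= thr) {
        if (y[j] == 1) tp <- tp + 1 else fp <- fp + 1
      } else {
        if (y[j] == 1) fn <- fn + 1 else tn <- tn + 1
      }
    }
    expect_equal(unclass(cc), list(TP = tp, FP = fp, TN = tn, FN = fn, N = n))
  }
  expect_error(confusion(c(1, 0), c(0.5, 0.5, 0.5)), "mismatch")
})

test_that("threshold metrics satisfy their defining identities", {
  cc <- structure(list(TP = 96, FP = 58, TN = 82, FN = 4, N = 240),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$ACC, 0.7417, tolerance = 5e-5)
  expect_equal(m$PRE, 0.6234, tolerance = 5e-5)
  expect_equal(m$SEN, 0.96)
  expect_equal(m$F1, 2 * m$PRE * m$SEN / (m$PRE + m$SEN))
  # all-positive degenerate classifier
  y <- c(rep(1, 100), rep(0, 140))
  d <- classification_metrics(confusion(y, rep(0.9, 240), 0.5))
  expect_equal(d$SEN, 1)
  expect_equal(d$SPE, 0)
  expect_equal(d$ACC, mean(y))
  # no predicted positives: precision convention
  expect_warning(z <- classification_metrics(confusion(y, rep(0.1, 240), 0.5)),
                 "undefined")
  expect_equal(z$PRE, 0)
  set.seed(6)
  for (i in 1:25) {
    y <- rbinom(30, 1, 0.5); p <- runif(30)
    if (length(unique(y)) < 2) next
    m <- suppressWarnings(classification_metrics(confusion(y, p, 0.5)))
    if (m$PRE + m$SEN > 0) {
      expect_equal(m$F1, 2 * m$PRE * m$SEN / (m$PRE + m$SEN))
    }
  }
})

test_that("ROC-AUC equals pair counting and pROC; PR-AUC follows the step rule", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # ties likely
    pos <- p[y == 1]; neg <- p[y == 0]
    u <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
    expect_equal(roc_auc(y, p), u)
  }
  set.seed(52)
  y <- rbinom(200, 1, 0.3); p <- runif(200)
  expect_equal(roc_auc(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
  # perfect separation and constant scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(pr_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # hand-computed step-rule average precision
  expect_equal(pr_auc(c(1, 0, 1), c(0.9, 0.8, 0.7)), 0.5 * 1 + 0.5 * (2 / 3))
  # label/score flip symmetry
  set.seed(53)
  y <- rbinom(60, 1, 0.4); p <- runif(60)
  expect_equal(roc_auc(y, p), roc_auc(1 - y, 1 - p))
})

test_that("Brier score and calibration bins behave as defined", {
  y <- c(1, 0, 1, 0)
  expect_equal(brier_calibration(y, y)$brier, 0)
  expect_equal(brier_calibration(y, rep(0.5, 4))$brier, 0.25)
  set.seed(61)
  y <- rbinom(300, 1, 0.3); p <- runif(300)
  cal <- brier_calibration(y, p, bins = 10)
  expect_equal(sum(cal$bins$count), 300)
  expect_true(all(cal$bins$mean_pred >= cal$bins$lower - 1e-12, na.rm = TRUE))
  expect_true(all(cal$bins$mean_pred <= cal$bins$upper + 1e-12, na.rm = TRUE))
  # Murphy decomposition on the binned forecasts:
  # brier = reliability - resolution + uncertainty (exact when forecasts
  # take the bin-mean values)
  pb <- cal$bins$mean_pred[findInterval(p, seq(0, 1, 0.1),
                                        rightmost.closed = TRUE)]
  cal2 <- brier_calibration(y, pb, bins = 10)
  ok <- cal$bins$count > 0
  wt <- cal$bins$count[ok] / 300
  rel <- sum(wt * (cal$bins$mean_pred[ok] - cal$bins$observed[ok])^2)
  res <- sum(wt * (cal$bins$observed[ok] - mean(y))^2)
  unc <- mean(y) * (1 - mean(y))
  expect_equal(cal2$brier, rel - res + unc, tolerance = 1e-12)
})

test_that("net benefit follows its closed forms", {
  cc <- structure(list(TP = 96, FP = 58, TN = 82, FN = 4, N = 240),
                  class = "confusion_counts")
  expect_equal(net_benefit(cc, 0.2), 0.4 - (58 / 240) * 0.25)
  cc0 <- structure(list(TP = 30, FP = 0, TN = 60, FN = 10, N = 100),
                   class = "confusion_counts")
  for (pt in c(0.05, 0.3, 0.8)) expect_equal(net_benefit(cc0, pt), 0.3)
  none <- structure(list(TP = 0, FP = 0, TN = 70, FN = 30, N = 100),
                    class = "confusion_counts")
  expect_equal(net_benefit(none, 0.4), 0)
  expect_error(net_benefit(cc, 1.2), "p_t")
})

test_that("decision curves track the reference strategies", {
  set.seed(71)
  y <- rbinom(150, 1, 0.35)
  p <- plogis(qlogis(0.35) + 2 * (y - 0.35) + rnorm(150, 0, 0.8))
  curve <- dca_curve(y, p)
  expect_equal(unique(curve$nb_none), 0)
  prev <- mean(y)
  i <- which.min(abs(curve$threshold - prev))
  expect_equal(curve$nb_all[i], prev - (1 - prev) * curve$threshold[i] /
                 (1 - curve$threshold[i]), tolerance = 1e-12)
  expect_lt(abs(curve$nb_all[i]), 0.02)  # zero crossing at the prevalence
  # a perfect predictor dominates both references everywhere
  perfect <- dca_curve(y, y * 0.999 + 0.0005)
  expect_true(all(perfect$nb_model >= perfect$nb_all - 1e-12))
  expect_true(all(perfect$nb_model >= 0))
  # permutation invariance of the whole report
  ord <- sample(length(y))
  expect_equal(dca_curve(y[ord], p[ord])$nb_model, curve$nb_model)
  m1 <- metrics_report(y, p)
  m2 <- metrics_report(y[ord], p[ord])
  expect_equal(m1, m2)
})
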