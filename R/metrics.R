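#' Confusion counts at a probability threshold
#'
#' Predicted positive iff `p >= threshold` (ties count as positive).
#'
#' @param y binary outcome vector (0/1).
#' @param p predicted probability vector.
#' @param threshold decision threshold in (0, 1).
#' @return object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`,
#'   `N`.
#' @export
confusion <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) stop("length mismatch", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  pred <- p >= threshold
  structure(list(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
                 TN = sum(!pred & y == 0), FN = sum(!pred & y == 1),
                 N = length(y)),
            class = "confusion_counts")
}

#' Threshold classification metrics from confusion counts
#'
#' Precision, sensitivity (recall), specificity, accuracy and F1. The 0/0
#' convention: an undefined precision (no predicted positives) is reported
#' as 0 with a warning; F1 is 0 when precision + sensitivity is 0.
#'
#' @param c a `confusion_counts`.
#' @return list with `PRE`, `SEN`, `SPE`, `ACC`, `F1`.
#' @export
classification_metrics <- function(c) {
  stopifnot(c$N > 0)
  pre <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else {
    warning("no predicted positives: precision undefined, reported as 0",
            call. = FALSE)
    0
  }
  sen <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else 0
  spe <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else 0
  acc <- (c$TP + c$TN) / c$N
  f1 <- if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0
  list(PRE = pre, SEN = sen, SPE = spe, ACC = acc, F1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a positive outranks a
#' negative, with ties counted 1/2 — identical to the trapezoid over all
#' thresholds.
#'
#' @param y binary outcome vector.
#' @param p score/probability vector.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC-AUC", call. = FALSE)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision step rule: precision at each distinct positive,
#' weighted by the recall increment — avoids the optimism of linear PR
#' interpolation.
#'
#' @param y binary outcome vector.
#' @param p score/probability vector.
#' @return scalar PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) {
    stop("both classes required for PR-AUC", call. = FALSE)
  }
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  prec <- tp / (tp + fp)
  rec <- tp / n1
  # collapse tied scores to the last index of each tie block
  last <- c(ps[-1] != ps[-length(ps)], TRUE)
  prec <- prec[last]; rec <- rec[last]
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Brier score and calibration curve
#'
#' Mean squared error of the probability forecasts plus a reliability
#' summary over equal-width probability bins: per bin, the mean predicted
#' probability, the observed event fraction and the count. Empty bins are
#' kept in the table with zero count.
#'
#' @param y binary outcome vector.
#' @param p probability vector in \[0, 1\].
#' @param bins number of equal-width bins (default 10).
#' @return object of class `calibration_curve` with `brier` and a `bins`
#'   data.frame.
#' @export
brier_calibration <- function(y, p, bins = 10L) {
  stopifnot(all(p >= 0), all(p <= 1), length(y) == length(p))
  brier <- mean((p - y)^2)
  edges <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), bins)
  tab <- data.frame(
    bin = seq_len(bins),
    lower = edges[-(bins + 1)], upper = edges[-1],
    mean_pred = vapply(seq_len(bins),
                       function(b) if (any(idx == b)) mean(p[idx == b]) else NA_real_,
                       numeric(1)),
    observed = vapply(seq_len(bins),
                      function(b) if (any(idx == b)) mean(y[idx == b]) else NA_real_,
                      numeric(1)),
    count = vapply(seq_len(bins), function(b) sum(idx == b), integer(1))
  )
  structure(list(brier = brier, bins = tab, n = length(y)),
            class = "calibration_curve")
}

#' Decision-curve net benefit at one threshold
#'
#' `NB = TP/N - (FP/N) * p_t / (1 - p_t)`: the benefit of true positives
#' traded against false positives at the harm-benefit ratio implied by the
#' risk threshold `p_t`.
#'
#' @param c a `confusion_counts`.
#' @param p_t risk threshold in (0, 1).
#' @return scalar net benefit.
#' @export
net_benefit <- function(c, p_t) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie in (0, 1)", call. = FALSE)
  c$TP / c$N - (c$FP / c$N) * p_t / (1 - p_t)
}

#' Decision curve over a threshold grid
#'
#' For each threshold the model treats iff `p >= p_t`; reference lines are
#' treat-all (`NB_all = prevalence - (1 - prevalence) p_t / (1 - p_t)`,
#' crossing zero at the prevalence) and treat-none (`NB_none = 0`).
#'
#' @param y binary outcome vector.
#' @param p probability vector.
#' @param thresholds grid inside (0, 1); default 0.01..0.99 by 0.01.
#' @return object of class `net_benefit_curve`: data.frame with columns
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
dca_curve <- function(y, p, thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  prev <- mean(y)
  rows <- lapply(thresholds, function(pt) {
    cc <- confusion(y, p, pt)
    data.frame(threshold = pt,
               nb_model = net_benefit(cc, pt),
               nb_all = prev - (1 - prev) * pt / (1 - pt),
               nb_none = 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Full metrics report for one probability vector
#'
#' @param y binary outcome vector.
#' @param p probability vector.
#' @param threshold decision threshold for the confusion metrics.
#' @return named list: `PRE`, `SEN`, `SPE`, `ACC`, `F1`, `ROC_AUC`,
#'   `PR_AUC`.
#' @export
metrics_report <- function(y, p, threshold = 0.5) {
  m <- classification_metrics(confusion(y, p, threshold))
  m$ROC_AUC <- roc_auc(y, p)
  m$PR_AUC <- pr_auc(y, p)
  m
}
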