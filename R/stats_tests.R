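#' Pooled two-sample t test from group summaries
#'
#' Student's pooled-variance two-sample t statistic computed from group
#' summaries (n, mean, sd), with a two-tailed p-value on
#' `n1 + n2 - 2` degrees of freedom. The statistic is reported as a
#' magnitude, matching baseline-characteristics tables.
#'
#' @param n1,mean1,sd1 size, mean and SD of group 1.
#' @param n2,mean2,sd2 size, mean and SD of group 2.
#' @return list with `statistic` (t) and `p_value`.
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(list(statistic = 0, p_value = 1))
    }
    stop("zero pooled variance with unequal means: infinite statistic",
         call. = FALSE)
  }
  se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  t <- abs(mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(statistic = t, p_value = 2 * stats::pt(-t, df))
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' expected counts from the margins and `k - 1` degrees of freedom.
#'
#' @param counts a 2 x k matrix of observed counts.
#' @return list with `statistic` (chi-square), `df` and `p_value`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) >= 2)
  if (any(rowSums(counts) <= 0) || any(colSums(counts) <= 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- ncol(counts) - 1
  list(statistic = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with mid-rank tie handling. Exact p-value when the smaller
#' sample has at most 8 observations and there are no ties, otherwise a
#' tie-corrected normal approximation. The reported U is the smaller of the
#' two orientations.
#'
#' @param x,y numeric sample vectors.
#' @return list with `statistic` (U) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  u <- min(u_x, u_y)
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (min(nx, ny) <= 8 && !has_ties) {
    p <- min(1, 2 * stats::pwilcox(u, nx, ny))
  } else {
    n <- nx + ny
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    mu <- nx * ny / 2
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (abs(u_x - mu) - 0.5) / sqrt(sigma2)  # continuity correction
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
  }
  list(statistic = u, p_value = min(p, 1))
}

#' Summary statistics for one cohort variable
#'
#' Dispatch by schema kind: mean/sd for normal continuous variables,
#' median and quartiles for skewed ones, level counts for binary,
#' categorical and count variables.
#'
#' @param values vector of values.
#' @param var a `variable_schema`.
#' @return list of class `summary_stats`.
#' @export
summary_stats <- function(values, var) {
  out <- list(name = var$name, kind = var$kind, n = length(values))
  if (var$kind == "continuous_normal") {
    out$mean <- mean(values)
    out$sd <- stats::sd(values)
  } else if (var$kind == "continuous_skewed") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out$q1 <- q[1]; out$median <- q[2]; out$q3 <- q[3]
  } else {
    tab <- if (var$kind == "categorical") {
      table(factor(values, levels = var$categories))
    } else {
      table(values)
    }
    out$level_counts <- as.integer(tab)
    names(out$level_counts) <- names(tab)
  }
  structure(out, class = "summary_stats")
}

# group comparison for one variable; dispatch per schema kind, with a
# Shapiro-Wilk normality gate (alpha = 0.05 per group) deciding between the
# pooled t and the Mann-Whitney U for continuous variables.
compare_variable <- function(x_train, x_test, var) {
  kind <- var$kind
  if (kind %in% c("continuous_normal", "continuous_skewed")) {
    if (stats::sd(x_train) == 0 && stats::sd(x_test) == 0 &&
        mean(x_train) == mean(x_test)) {
      return(list(test = "pooled_t", statistic = 0, p_value = 1))
    }
    normal <- tryCatch(
      stats::shapiro.test(x_train)$p.value > 0.05 &&
        stats::shapiro.test(x_test)$p.value > 0.05,
      error = function(e) FALSE)
    if (normal) {
      r <- pooled_t_from_summary(length(x_train), mean(x_train), stats::sd(x_train),
                                 length(x_test), mean(x_test), stats::sd(x_test))
      list(test = "pooled_t", statistic = r$statistic, p_value = r$p_value)
    } else {
      r <- mann_whitney_u(x_train, x_test)
      list(test = "mann_whitney_u", statistic = r$statistic, p_value = r$p_value)
    }
  } else {
    levels <- if (kind == "categorical") var$categories else
      sort(unique(c(x_train, x_test)))
    tab <- rbind(table(factor(x_train, levels = levels)),
                 table(factor(x_test, levels = levels)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      return(list(test = "pearson_chi2", statistic = 0, p_value = 1))
    }
    r <- pearson_chi2(tab)
    list(test = "pearson_chi2", statistic = r$statistic, p_value = r$p_value)
  }
}

#' Baseline-characteristics comparison table
#'
#' Compares every schema variable (and the outcome) between the training
#' and testing partitions of a split, choosing the test by variable kind:
#' pooled t for continuous variables normal in both groups (Shapiro-Wilk at
#' alpha 0.05), Mann-Whitney U otherwise, and uncorrected Pearson
#' chi-square for binary/categorical/count variables.
#'
#' @param table a `cohort_table`.
#' @param split a `split_result` for `table`.
#' @return data.frame with columns `variable`, `test`, `statistic`,
#'   `p_value`.
#' @export
baseline_table <- function(table, split) {
  stopifnot(inherits(split, "split_result"))
  tr <- table$data[split$train_index, , drop = FALSE]
  te <- table$data[split$test_index, , drop = FALSE]
  rows <- lapply(table$schema, function(v) {
    xt <- tr[[v$name]]; xe <- te[[v$name]]
    if (is.factor(xt)) { xt <- as.character(xt); xe <- as.character(xe) }
    r <- compare_variable(xt, xe, v)
    data.frame(variable = v$name, test = r$test,
               statistic = r$statistic, p_value = r$p_value)
  })
  out_r <- compare_variable(table$outcome[split$train_index],
                            table$outcome[split$test_index],
                            variable_schema("occlusion", "binary"))
  out <- rbind(data.frame(variable = "occlusion", test = out_r$test,
                          statistic = out_r$statistic, p_value = out_r$p_value),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
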