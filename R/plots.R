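# ggplot2 renderings of the evaluation and interpretability curves.

#' Plot a decision curve
#'
#' @param curve a `net_benefit_curve` from [dca_curve()].
#' @return a ggplot object.
#' @export
plot_dca <- function(curve) {
  df <- as.data.frame(curve)
  long <- rbind(
    data.frame(threshold = df$threshold, nb = df$nb_model, strategy = "model"),
    data.frame(threshold = df$threshold, nb = df$nb_all, strategy = "treat all"),
    data.frame(threshold = df$threshold, nb = df$nb_none, strategy = "treat none"))
  ggplot2::ggplot(long, ggplot2::aes(x = threshold, y = nb,
                                     colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "risk threshold", y = "net benefit") +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' @param cal a `calibration_curve` from [brier_calibration()].
#' @return a ggplot object.
#' @export
plot_calibration <- function(cal) {
  df <- cal$bins[cal$bins$count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = mean_pred, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(size = count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean predicted probability",
                  y = "observed event fraction",
                  title = sprintf("Brier score %.3f", cal$brier)) +
    ggplot2::theme_minimal()
}

#' Plot an L1 regularisation path and its CV curve
#'
#' @param path a `lasso_path`.
#' @return a ggplot object (coefficient trajectories; the CV curve is in
#'   `path$cv_mean`).
#' @export
plot_lasso_path <- function(path) {
  b <- path$beta
  long <- do.call(rbind, lapply(rownames(b), function(f) {
    data.frame(feature = f, lambda = path$lambda, coef = b[f, ])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = log(lambda), y = coef,
                                     group = feature)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log(path$lambda_1se), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a Shapley importance ranking
#'
#' @param importance data.frame from [shap_importance()].
#' @param top show the top-n features.
#' @return a ggplot object.
#' @export
plot_shap_importance <- function(importance, top = 15L) {
  df <- utils::head(importance, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = importance, y = feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL) +
    ggplot2::theme_minimal()
}
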