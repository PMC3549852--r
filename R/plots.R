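# ggplot2 visualisations of sweep, CV and regression results.

#' Plot a window-size sweep
#'
#' Accuracy and MCC against the sequence-window width, with the best size (by
#' MCC) highlighted.
#'
#' @param object A `stab_sweep` object from [window_size_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stab_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("window_size", "acc", "mcc")],
                            c("acc", "mcc"), names_to = "metric")
  best <- attr(object, "best_size")
  ggplot2::ggplot(df, ggplot2::aes(window_size, value, colour = metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = unique(df$window_size)) +
    ggplot2::labs(x = "window size (residues)", y = NULL,
                  title = "Meta-classifier performance vs sequence window size",
                  subtitle = paste0("dashed: best MCC at window ", best)) +
    ggplot2::theme_minimal()
}

#' Plot pooled cross-validation metrics
#'
#' @param object A `stab_cv` object.
#' @param ... Unused.
#' @return A ggplot bar chart of Sn, Sp, Acc, MCC.
#' @export
autoplot.stab_cv <- function(object, ...) {
  m <- object$metrics
  df <- tibble(metric = factor(c("Sn", "Sp", "Acc", "MCC"),
                               levels = c("Sn", "Sp", "Acc", "MCC")),
               value = c(m$sn, m$sp, m$acc, m$mcc))
  ggplot2::ggplot(df, ggplot2::aes(metric, value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", value)),
                       vjust = -0.4, size = 3) +
    ggplot2::ylim(NA, 1.05) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-fold CV, mode %s (n = %d)",
                                  object$config$k, object$config$mode,
                                  object$config$n)) +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted ddG correlation plot
#'
#' @param observed,predicted Numeric ddG vectors (kcal/mol).
#' @return A ggplot scatter with the identity line and the Pearson r in the
#'   subtitle.
#' @export
plot_ddg_correlation <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  r <- cor(observed[ok], predicted[ok])
  ggplot2::ggplot(tibble(observed = observed[ok], predicted = predicted[ok]),
                  ggplot2::aes(observed, predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "observed ddG (kcal/mol)",
                  y = "predicted ddG (kcal/mol)",
                  title = "ddG regression",
                  subtitle = sprintf("Pearson r = %.3f", r)) +
    ggplot2::theme_minimal()
}
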