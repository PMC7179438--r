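#' Observed-versus-predicted plot for a fitted QSAR model
#'
#' @param object A `qsar_fit` from [fit_qsar()].
#' @param ... Unused.
#' @return A ggplot: training observations against fitted pEC50 with the
#'   identity line.
#' @method autoplot qsar_fit
#' @export
autoplot.qsar_fit <- function(object, ...) {
  df <- tibble(observed = object$observed, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Predicted pEC50", y = "Observed pEC50",
      title = paste0("OLS fit: ", paste(object$descriptors, collapse = " + ")),
      subtitle = sprintf("n = %d, r = %.4f, SEE = %.4f",
                         object$n_train, object$stats$r, object$stats$see)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of descriptor-activity correlations
#'
#' @param report A correlation report from [correlate_activity()].
#' @param cutoff Selection threshold drawn as reference lines (default:
#'   the report's cutoff).
#' @return A ggplot of Pearson r per descriptor.
#' @export
plot_correlations <- function(report, cutoff = attr(report, "cutoff") %||% 0.5) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$descriptor, .data$abs_r),
                               y = .data$r, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r with activity", fill = "Selected") +
    ggplot2::theme_minimal()
}

#' Recovery curve of a ranked screen
#'
#' @param screen A ranked screen tibble (see [ranked_screen()]).
#' @param highlight_k Optional ranks to mark with vertical lines.
#' @return A ggplot of percent agonists recovered against rank cutoff k.
#' @export
plot_recovery <- function(screen, highlight_k = NULL) {
  curve <- recovery_curve(screen)
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$k,
                                    y = .data$percent_agonists_recovered)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Rank cutoff k", y = "Agonists recovered (%)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight_k)) {
    p <- p + ggplot2::geom_vline(xintercept = highlight_k, linetype = 3)
  }
  p
}
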