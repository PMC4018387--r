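#' Plot discriminant coefficients
#'
#' Lollipop plot of the fitted discriminant direction(s), faceted by task
#' for joint fits. Zero coefficients (dropped features) show at zero.
#'
#' @param object An `mlpd_fit` or `slpd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mlpd_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$global, y = .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$global, yend = 0),
                          colour = "grey50") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~task_id, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "global feature index",
                  y = "discriminant coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mlpd_fit
#' @exportS3Method ggplot2::autoplot
autoplot.slpd_fit <- function(object, ...) {
  d <- dplyr::mutate(tidy(object), task_id = 1L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$global, y = .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$global, yend = 0),
                          colour = "grey50") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "global feature index",
                  y = "discriminant coefficient") +
    ggplot2::theme_minimal()
}

#' Plot repeated cross-validation metrics
#'
#' Mean metric per scope with +/- 1 sd error bars over repetitions.
#'
#' @param object A `cv_summary` from [repeated_cv_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_summary <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$mean,
                                  fill = .data$scope)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Repeated cross-validation performance") +
    ggplot2::theme_minimal()
}

#' Histogram of cross-block canonical correlations
#'
#' Visualises the dependence between two feature blocks of a complete-
#' pattern task via [canonical_correlation_diagnostic()]; strong
#' correlations are the regime where joint multi-task fitting is expected
#' to transfer information across tasks.
#'
#' @param t A `task_dataset` containing both blocks.
#' @param split Number of leading columns forming the first block.
#' @return A ggplot object.
#' @export
plot_canonical_correlations <- function(t, split) {
  cc <- canonical_correlation_diagnostic(t, split)
  ggplot2::ggplot(tibble::tibble(cc = cc), ggplot2::aes(x = .data$cc)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "canonical correlation", y = "count") +
    ggplot2::theme_minimal()
}
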