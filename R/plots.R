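# ggplot2 displays for run- and participant-level results.

#' Bar chart of group decoding accuracy above chance
#'
#' Percentage-above-chance group accuracy with standard-error bars, one
#' bar per region, faceted by analysis — the standard summary display
#' for region-of-interest decoding studies.
#'
#' @param run A `ps_run` from [run_all()], or its `group` tibble.
#' @return A ggplot object.
#' @export
plot_group_accuracy <- function(run) {
  grp <- if (inherits(run, "ps_run")) run$group else run
  sem_pct <- 100 * grp$sem
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$roi,
                                    y = .data$pct_above_chance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pct_above_chance - sem_pct,
                                        ymax = .data$pct_above_chance + sem_pct),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~analysis) +
    ggplot2::labs(x = "region of interest",
                  y = "accuracy above chance (%)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_group_accuracy
#' @param object,... `autoplot` method arguments.
#' @method autoplot ps_run
#' @export
autoplot.ps_run <- function(object, ...) plot_group_accuracy(object)

#' Confusion-matrix heatmap for a decoding result
#'
#' @param object A `ps_decoding`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ps_decoding
#' @export
autoplot.ps_decoding <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("participant %s, %s",
                                  format(object$participant),
                                  format(object$roi)),
                  x = "predicted memory", y = "true memory") +
    ggplot2::theme_minimal()
}
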