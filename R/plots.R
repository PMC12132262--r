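#' Boxplots of a parameter-recovery experiment
#'
#' One panel per estimated parameter; boxplots of the replicate estimates at
#' each setting with the true value marked by a dashed line (drawn per panel
#' when the truth is constant within an estimator). The x-axis is the
#' quantity the experiment varied.
#'
#' @param object A `rates_experiment` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rates_experiment <- function(object, ...) {
  mode <- object$mode[1]
  xvar <- switch(mode,
    k_sweep = "k",
    length_sweep = "L",
    composition_sweep = "frac_A",
    "truth"
  )
  df <- dplyr::filter(object, !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data[[xvar]]), y = .data$estimate
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(
      data = dplyr::distinct(df, .data$estimator, .data$truth),
      ggplot2::aes(yintercept = .data$truth),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~estimator, scales = "free_y") +
    ggplot2::labs(x = xvar, y = "estimate",
                  title = sprintf("Parameter recovery (%s)", mode)) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.rates_experiment
#' @param table A `rates_experiment` tibble.
#' @export
plot_experiment <- function(table, ...) {
  autoplot.rates_experiment(table, ...)
}
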