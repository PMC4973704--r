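#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of basic-parameter estimates
#'
#' @param object An [nma_fit()] object.
#' @param conf.level Confidence level for the interval whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nma_fit <- function(object, conf.level = object$level, ...) {
  td <- generics::tidy(object, conf.level = conf.level)
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate, y = .data$term,
    xmin = .data$conf.low, xmax = .data$conf.high
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = sprintf(
        "Average treatment effect (%s model, %.0f%% CI)",
        object$model, 100 * conf.level
      ),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of treatment ranking probabilities
#'
#' @param object An [nma_rank()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nma_rank <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$rank), y = .data$treatment, fill = .data$prob
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(
      x = "Rank (1 = most effective)", y = NULL, fill = "Probability",
      subtitle = sprintf("direction: %s", attr(object, "direction"))
    ) +
    ggplot2::theme_minimal()
}

#' Coverage summary plot for a simulation study
#'
#' @param object An `nma_sim` tibble from [run_simulation_study()].
#' @param ... Unused.
#' @return A ggplot object showing estimated coverage per grid cell and
#'   parameter against the nominal level.
#' @export
autoplot.nma_sim <- function(object, ...) {
  lv <- attr(object, "level")
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$tau_beta_sq), y = .data$coverage,
    colour = .data$parameter, group = .data$parameter
  )) +
    ggplot2::geom_hline(yintercept = lv, linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~tau_omega_sq,
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "Heterogeneity variance", y = "Estimated coverage",
      colour = "Basic parameter"
    ) +
    ggplot2::theme_minimal()
}
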