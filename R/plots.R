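#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot view of each result type: a
#' risk map (O vs D, point size by RPN when severity is available) for
#' `risk_estimates`, interval plots for `rpn_boot`, and truth-vs-estimate
#' bias bars for `bias_experiment`.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name qcrpn-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname qcrpn-autoplot
#' @export
autoplot.risk_estimates <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$status == "ok")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$o_continuous,
                                        y = .data$d_continuous,
                                        label = .data$fm_id))
  p <- if (all(is.na(df$rpn))) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(size = .data$rpn))
  p +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(xlim = c(1, 10), ylim = c(1, 10)) +
    ggplot2::labs(x = "occurrence score (continuous)",
                  y = "detectability score (continuous)") +
    ggplot2::theme_minimal()
}

#' @rdname qcrpn-autoplot
#' @export
autoplot.rpn_boot <- function(object, ...) {
  ggplot2::ggplot(object$intervals,
                  ggplot2::aes(x = .data$quantity, y = .data$estimate,
                               ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = sprintf("Parametric bootstrap, %.0f%% intervals",
                                  100 * object$level)) +
    ggplot2::theme_minimal()
}

#' @rdname qcrpn-autoplot
#' @export
autoplot.bias_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("n0_bias", "undetected_prob_bias"),
    names_to = "quantity", values_to = "bias"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$bias)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean estimate - truth") +
    ggplot2::theme_minimal()
}
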