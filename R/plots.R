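#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the parameter estimates of a GSCA fit
#'
#' Dot plot of weights, loadings and path coefficients by component.
#'
#' @param object A `gsca_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsca_fit <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$type %in% c("weight", "loading", "path"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = "estimate", y = NULL)
}

#' Plot bootstrap estimates with confidence intervals
#'
#' @param object A `gsca_bootstrap`.
#' @param types Parameter types to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsca_bootstrap <- function(object,
                                    types = c("weight", "loading", "path"),
                                    ...) {
  d <- dplyr::filter(object$estimates, .data$type %in% types)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = "estimate (95% percentile CI)", y = NULL)
}

#' Plot recovery-study error against sample size
#'
#' RMSE (solid) and absolute bias (dashed) per parameter family.
#'
#' @param object A `gsca_recovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsca_recovery <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary, c("abs_bias", "rmse"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$N, y = .data$value,
                                  colour = .data$family,
                                  linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sample size", y = "error")
}
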