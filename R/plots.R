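#' Plot a profile prediction
#'
#' Dot-and-interval panels of the posterior choice and success
#' probabilities per patch (mean and HPD), mirroring the standard
#' presentation of counterfactual harvester profiles.
#'
#' @param object A `"profile_prediction"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_prediction
#' @export
autoplot.profile_prediction <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    dplyr::transmute(s, patch = .data$patch, quantity = "choice",
                     mean = .data$choice_mean, lo = .data$choice_lo,
                     hi = .data$choice_hi),
    dplyr::transmute(s, patch = .data$patch, quantity = "success",
                     mean = .data$success_mean, lo = .data$success_lo,
                     hi = .data$success_hi)
  )
  long$patch <- factor(long$patch, levels = s$patch)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$patch)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::facet_wrap(~quantity, nrow = 1) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "posterior probability", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.profile_prediction
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot income-sweep curves
#'
#' Posterior-mean choice probability per patch as a function of raw
#' household income, with HPD ribbons.
#'
#' @param sweep A tibble from [income_sweep()].
#' @param quantity `"choice"` or `"success"`.
#' @return A ggplot object.
#' @export
plot_income_sweep <- function(sweep, quantity = c("choice", "success")) {
  quantity <- match.arg(quantity)
  mean_col <- paste0(quantity, "_mean")
  lo_col <- paste0(quantity, "_lo")
  hi_col <- paste0(quantity, "_hi")
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$income,
                                      y = .data[[mean_col]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo_col]],
                                      ymax = .data[[hi_col]]),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~patch) +
    ggplot2::labs(x = "household income (raw units)",
                  y = paste("posterior", quantity, "probability")) +
    ggplot2::theme_minimal()
}
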