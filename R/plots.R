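#' Plot simulation results
#'
#' Displays, per method, either the average estimate against the number of
#' clusters per arm (with the true value as a horizontal reference line and
#' +/- 2 Monte-Carlo-error bars) or the coverage of the nominal 95\%
#' confidence intervals (reference line at 95), one colour per
#' missing-data handling.
#'
#' @param object A `crt_sim_results` tibble from [run_study()].
#' @param type `"estimate"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crt_sim_results <- function(object, type = c("estimate", "coverage"),
                                     ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  if (type == "estimate") {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$k, y = .data$mean_estimate, colour = .data$handling)) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$true_value),
                          linetype = 2, colour = "grey40") +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_estimate - 2 * .data$mc_error_estimate,
        ymax = .data$mean_estimate + 2 * .data$mc_error_estimate),
        width = 0.1) +
      ggplot2::labs(y = "average estimate", x = "clusters per arm")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$k, y = .data$coverage_pct, colour = .data$handling)) +
      ggplot2::geom_hline(yintercept = 95, linetype = 2, colour = "grey40") +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::labs(y = "coverage of nominal 95% CI (%)",
                    x = "clusters per arm")
  }
  p + ggplot2::facet_wrap(~method_id, scales = "free_y") +
    ggplot2::scale_x_log10(breaks = sort(unique(df$k))) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
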