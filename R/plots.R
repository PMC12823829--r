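#' Plot a deterministic survival curve
#'
#' @param params A [decay_params()] object.
#' @param t_max,step Time grid extent and spacing in minutes.
#' @return A ggplot object showing survival (%) against response time.
#' @export
plot_survival_curve <- function(params = decay_params(), t_max = 40, step = 0.5) {
  require_ggplot2()
  curve <- survival_curve(params, seq(0, t_max, by = step))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t_min, y = 100 * .data$survival)) +
    ggplot2::geom_line(linewidth = 1, colour = "#b2182b") +
    ggplot2::labs(x = "Response time (minutes)", y = "Survival probability (%)",
                  title = "Survival after cardiac arrest vs. treatment delay") +
    ggplot2::theme_minimal()
}

#' Plot a simulated survival curve with its simulation interval
#'
#' @param summary An `mc_summary` from [simulate_curve()].
#' @param title Plot title (e.g. the municipality name).
#' @return A ggplot object: the Monte Carlo mean with a shaded band
#'   between the configured percentiles.
#' @export
plot_mc_curve <- function(summary, title = NULL) {
  require_ggplot2()
  df <- tibble::as_tibble(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$lower,
                                      ymax = 100 * .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$mean),
                       colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "Response time (minutes)", y = "Survival probability (%)",
                  title = title) +
    ggplot2::theme_minimal()
}

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

# silence R CMD check NOTE for ggplot2's .data pronoun
utils::globalVariables(".data")
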