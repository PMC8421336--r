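# Figures: sweep summaries and single-run time series. ggplot2 is optional.

utils::globalVariables(c("w_f_post", "delta_alpha", "model", "t", "alpha",
                         "agent_id", "gender", "theta", "household_id"))

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package `ggplot2` is required for plotting", call. = FALSE)
}

#' Plot a wage sweep
#'
#' Per-agent behaviour changes (points) and the per-wage mean (line),
#' faceted by gender.
#'
#' @param sweep an `hh_sweep` from [wage_sweep()] (or several row-bound
#'   together; colour distinguishes `model`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  .need_ggplot()
  means <- aggregate(delta_alpha ~ model + gender + w_f_post, data = sweep,
                     FUN = mean)
  ggplot2::ggplot(sweep, ggplot2::aes(x = w_f_post, y = delta_alpha,
                                      colour = model)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = means) +
    ggplot2::facet_wrap(~gender) +
    ggplot2::labs(x = "post-change female wage",
                  y = "change in private-activity time (post-change to end)") +
    ggplot2::theme_minimal()
}

#' Plot a simulation time series
#'
#' Private-activity time per agent (coloured by gender) and the household
#' transfer fractions (black), over time.
#'
#' @param series an `hh_series` from [run_model()].
#' @param households optional household ids to restrict the theta lines to.
#' @return A ggplot object.
#' @export
plot_timeseries <- function(series, households = NULL) {
  .need_ggplot()
  th <- unique(series[, c("t", "household_id", "theta")])
  if (!is.null(households))
    th <- th[th$household_id %in% households, ]
  ggplot2::ggplot(series,
                  ggplot2::aes(x = t, y = alpha, group = agent_id,
                               colour = gender)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = th,
                       mapping = ggplot2::aes(x = t, y = theta,
                                              group = household_id),
                       colour = "black", alpha = 0.3, linewidth = 0.3,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "time step",
                  y = "private-activity time (colour) / transfer (black)") +
    ggplot2::theme_minimal()
}
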