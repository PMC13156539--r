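#' Arm-mean trajectories of every instrument
#'
#' Observed per-arm means at each assessment for the six psychometric
#' instruments, faceted by instrument.
#'
#' @param panel an `outcome_panel`.
#' @return A ggplot object.
#' @export
plot_outcome_trajectories <- function(panel) {
  d <- as.data.frame(panel)
  vars <- setdiff(panel_instruments(panel), "utility")
  long <- do.call(rbind, lapply(vars, function(v) {
    ag <- stats::aggregate(d[[v]], list(arm = d$arm, timepoint = d$timepoint),
                           mean, na.rm = TRUE)
    ag$instrument <- toupper(v)
    names(ag)[3] <- "mean"
    ag
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                     colour = .data$arm,
                                     group = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~instrument, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "arm mean score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Bootstrap (incremental QALY, incremental cost) cloud with the
#' willingness-to-pay threshold line and the point estimate.
#'
#' @param result a [cea_evaluate()] result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result) {
  d <- as.data.frame(result$draws)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly,
                                  y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = result$threshold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::annotate("point", x = result$delta_qaly, y = result$delta_cost,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "incremental QALYs", y = "incremental cost (US$)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: US$%s/QALY",
                                     format(result$threshold,
                                            big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param result a [cea_evaluate()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(result) {
  ggplot2::ggplot(result$ceac, ggplot2::aes(x = .data$lambda,
                                            y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = result$threshold,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "willingness to pay (US$/QALY)",
                  y = "probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
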