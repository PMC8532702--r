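#' Goodness-of-fit panels
#'
#' Observed versus population and individual predictions, and conditional
#' weighted residuals versus population prediction and time after dose.
#'
#' @param g A data frame from [gof()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_gof <- function(g) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_gof requires ggplot2")
  long <- rbind(
    data.frame(panel = "obs vs PRED", x = g$pred, y = g$dv, ref = "identity"),
    data.frame(panel = "obs vs IPRED", x = g$ipred, y = g$dv, ref = "identity"),
    data.frame(panel = "CWRES vs PRED", x = g$pred, y = g$cwres, ref = "zero"),
    data.frame(panel = "CWRES vs TAD", x = g$tad, y = g$cwres, ref = "zero"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(
      data = data.frame(panel = c("obs vs PRED", "obs vs IPRED"),
                        slope = 1, intercept = 0),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      linetype = 2) +
    ggplot2::geom_hline(
      data = data.frame(panel = c("CWRES vs PRED", "CWRES vs TAD"), y0 = 0),
      ggplot2::aes(yintercept = .data$y0), linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Prediction-corrected VPC plot
#'
#' @param v A data frame from [pc_vpc()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_vpc <- function(v) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_vpc requires ggplot2")
  v$tad_mid <- (v$tad_lo + v$tad_hi) / 2
  v$pct <- factor(v$percentile)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$tad_mid, group = .data$pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    linetype = .data$pct)) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected concentration (mg/L)",
                  linetype = "observed percentile")
}
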