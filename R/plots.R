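# Diagnostic graphics (goodness of fit, NPDE, pcVPC), ggplot2-based.

#' Goodness-of-fit panel
#'
#' Four standard panels: observed versus population predictions, observed
#' versus individual predictions, conditional weighted residuals versus time
#' and versus population predictions.
#'
#' @param fit a [FitResult-class]
#' @param data the fitted [PKDataset-class]
#' @return a ggplot object (faceted)
#' @export
plotGof <- function(fit, data) {
  pt <- .predTable(fit, data)
  cw <- cwres(fit, data)
  d <- rbind(
    data.frame(x = pt$PRED, y = pt$DV, panel = "DV vs PRED", hline = NA),
    data.frame(x = pt$IPRED, y = pt$DV, panel = "DV vs IPRED", hline = NA),
    data.frame(x = cw$TIME, y = cw$CWRES, panel = "CWRES vs time", hline = 0),
    data.frame(x = pt$PRED, y = cw$CWRES, panel = "CWRES vs PRED", hline = 0))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(data = d[!is.na(d$hline), ],
                        ggplot2::aes(yintercept = .data$hline),
                        linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' NPDE distribution plots
#'
#' Histogram with the standard normal density and a QQ-plot against N(0,1).
#'
#' @param x an [NpdeResult-class]
#' @return a ggplot object
#' @export
plotNpde <- function(x) {
  v <- x@npde
  qq <- data.frame(theoretical = qnorm(stats::ppoints(length(v))),
                   sample = sort(v))
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical,
                                   y = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "N(0,1) quantiles", y = "NPDE",
                  title = sprintf("NPDE QQ-plot (mean %.3f, variance %.3f)",
                                  x@mean, x@variance)) +
    ggplot2::theme_bw()
}

#' Prediction-corrected VPC ribbon plot
#'
#' @param x a [VpcResult-class]
#' @return a ggplot object
#' @export
plotVpc <- function(x) {
  b <- x@bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo50, ymax = .data$hi50),
                         alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo5, ymax = .data$hi5),
                         alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs95), linetype = 2) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected concentration (mg/L)") +
    ggplot2::theme_bw()
}
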