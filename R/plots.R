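# Optional ggplot2 figures: CE plane, CEAC, tornado. ggplot2 is a soft
# dependency; every function errors cleanly when it is unavailable.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the CSV exports",
         call. = FALSE)
  }
}

#' Cost-effectiveness plane scatter
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay line to draw (yuan/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = wtp_threshold()) {
  need_ggplot()
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$points,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Incremental QALYs (AS - ES)",
                  y = "Incremental cost, yuan (AS - ES)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: WTP %s yuan/QALY",
                                     fmt_yuan(wtp)))
}

#' Cost-effectiveness acceptability curve
#'
#' @param ceac A [ceac_curve()] data frame (or a `psa_result`).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac) {
  need_ggplot()
  if (inherits(ceac, "psa_result")) ceac <- ceac$ceac
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness-to-pay, yuan/QALY",
                  y = "Probability AS is cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram
#'
#' @param tornado A [tornado_analysis()] result.
#' @param top Show the `top` widest bars (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15L) {
  need_ggplot()
  stopifnot(inherits(tornado, "tornado"))
  d <- utils::head(as.data.frame(tornado), top)
  d <- d[d$spread > 0, ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER, yuan/QALY", y = NULL,
                  title = "One-way sensitivity (tornado)",
                  subtitle = sprintf("dashed line: base-case ICER %s yuan/QALY",
                                     fmt_yuan(base)))
}
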