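# Figure analogues for the sensitivity analyses: tornado diagram,
# cost-effectiveness plane and acceptability curve.

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param tornado a [one_way_dsa()] result.
#' @param top number of parameters to display (most influential first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  stopifnot(inherits(tornado, "tornado_table"))
  base_icer <- attr(tornado, "base_icer")
  d <- utils::head(as.data.frame(tornado)[!is.na(tornado$width), ], top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_low, xend = .data$icer_high,
      y = .data$parameter, yend = .data$parameter), linewidth = 4,
      colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of the PSA draws
#'
#' @param psa a [run_psa()] result.
#' @param wtp willingness-to-pay thresholds drawn as reference lines
#'   through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = c(12516, 37547)) {
  stopifnot(inherits(psa, "psa_result"))
  p <- ggplot2::ggplot(psa$draws,
                       ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  for (w in wtp) {
    p <- p + ggplot2::geom_abline(slope = w, intercept = 0,
                                  linetype = "dashed", colour = "grey30")
  }
  p
}

#' Cost-effectiveness acceptability curve
#'
#' Shows the probability that the intervention (and, as its complement in a
#' two-strategy comparison, the comparator) is cost-effective as a function
#' of the willingness-to-pay threshold.
#'
#' @param psa a [run_psa()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  d <- rbind(
    data.frame(wtp = psa$ceac$wtp, probability = psa$ceac$probability,
               strategy = "intervention"),
    data.frame(wtp = psa$ceac$wtp, probability = 1 - psa$ceac$probability,
               strategy = "comparator")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$wtp, .data$probability,
                                  colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
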