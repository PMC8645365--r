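#' Plot the cost-effectiveness plane
#'
#' Strategies as points on the (QALY, cost) plane, labelled and coloured by
#' dominance status when the input is a ranked [rank_strategies()] table.
#'
#' @param object A `cea_eval` or `cea_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_eval
#' @export
autoplot.cea_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Cost (PPP $, discounted)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cea_eval
#' @method autoplot cea_table
#' @export
autoplot.cea_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qaly, y = .data$cost,
                                       colour = .data$status)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Cost (PPP $, discounted)",
                  colour = "Status", title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars from the low-perturbation ICER to the high-perturbation
#' ICER per parameter, widest at the top, with a vertical line at the base
#' ICER.
#'
#' @param object A `cea_owsa` from [run_owsa()].
#' @param top Show only the `top` widest parameters (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_owsa
#' @export
autoplot.cea_owsa <- function(object, top = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(top)) df <- head(df, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_icer, xend = .data$high_icer,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = df$base_icer[1], linetype = "dashed") +
    ggplot2::labs(x = "ICER (PPP $ / QALY)", y = NULL,
                  title = sprintf("Tornado: %s vs %s (+/-%.0f%%)",
                                  attr(object, "strategy"),
                                  attr(object, "comparator"),
                                  100 * attr(object, "rel_change"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cea_owsa
#' @export
plot_tornado <- function(object, top = NULL, ...) autoplot.cea_owsa(object, top = top, ...)

#' Cost-effectiveness acceptability curves
#'
#' Probability each strategy is optimal (highest net monetary benefit) as a
#' function of willingness to pay.
#'
#' @param object A `cea_ceac` from [ceac()].
#' @param wtp_ref Optional vertical reference line (e.g. 1x GDP per capita).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, wtp_ref = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$prob_optimal,
                                            colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Willingness to pay (PPP $ / QALY)",
                  y = "Probability cost-effective", colour = "Strategy",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(wtp_ref)) p <- p + ggplot2::geom_vline(xintercept = wtp_ref,
                                                      linetype = "dashed")
  p
}

#' @rdname autoplot.cea_ceac
#' @export
plot_ceac <- function(object, wtp_ref = NULL, ...) autoplot.cea_ceac(object, wtp_ref = wtp_ref, ...)

#' Incremental cost-effectiveness scatter plot
#'
#' Per-draw incremental (QALY, cost) points of strategy A over strategy B,
#' with the willingness-to-pay threshold line; points below the line are in
#' the acceptance region.
#'
#' @param psa A [run_psa()] result.
#' @param strategy_a,strategy_b Strategies compared (A minus B).
#' @param wtp Willingness-to-pay threshold drawn as a line through the
#'   origin; defaults to the parameter set's 1x GDP per capita.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, strategy_a, strategy_b, wtp = NULL) {
  if (is.null(wtp)) wtp <- attr(psa, "params")$config$gdp_per_capita
  sc <- psa_scatter_data(psa, strategy_a, strategy_b, wtp = wtp)
  frac <- mean(sc$accepted)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$incr_qaly, y = .data$incr_cost,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (PPP $)",
      colour = "Accepted",
      title = sprintf("%s vs %s: %.0f%% of draws in the acceptance region",
                      strategy_a, strategy_b, 100 * frac)
    ) +
    ggplot2::theme_minimal()
}
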