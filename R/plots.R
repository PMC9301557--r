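#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars spanning each lever's low/high ICER around the base-case
#' ICER, ordered by swing.
#'
#' @param object A `lcs_tornado` from [run_tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcs_tornado
#' @export
autoplot.lcs_tornado <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$parameter, yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (CNY/QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of PSA draws
#'
#' @param object A `lcs_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object: incremental QALYs against incremental cost,
#'   with the willingness-to-pay threshold line.
#' @method autoplot lcs_psa
#' @export
autoplot.lcs_psa <- function(object, ...) {
  thr <- object$summary$threshold
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, colour = "grey30") +
    ggplot2::geom_abline(slope = thr, intercept = 0,
                         colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `lcs_psa` from [run_psa()].
#' @return A ggplot object of the probability of cost-effectiveness against
#'   the willingness-to-pay threshold.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "lcs_psa"))
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$threshold,
                               y = .data$probability_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = psa$summary$threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' ICER versus start age for both screening intervals
#'
#' @param object A `lcs_grid` from [evaluate_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcs_grid
#' @export
autoplot.lcs_grid <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$interval != "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_age,
                                   y = .data$icer_vs_nonscreening,
                                   colour = .data$interval)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Start age (years)", y = "ICER vs nonscreening (CNY/QALY)",
                  colour = "Interval",
                  title = "ICER by screening start age") +
    ggplot2::theme_minimal()
}
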