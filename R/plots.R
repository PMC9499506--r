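#' Plot a clearance curve with its fitted slope
#'
#' @param series Tibble from [cleared_volume_series()].
#' @return A ggplot: cleared volume vs time with the OLS line.
#' @export
plot_clearance <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time_min, .data$cleared_uL)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "Time (min)", y = "Cleared volume (µL)") +
    ggplot2::theme_classic()
}

bar_theme <- function() {
  ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "bottom")
}

#' @describeIn analyze_permeability Bar chart of Pe (x 1e-3 cm/min) per
#'   condition, mean +/- SEM, faceted by assay temperature.
#' @param object A `pe_summary`.
#' @param ... Unused.
#' @export
autoplot.pe_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$condition_id,
                                       .data$pe_mean_scaled)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$pe_mean_scaled - .data$pe_sem * 1e3,
      ymax = .data$pe_mean_scaled + .data$pe_sem * 1e3), width = 0.25) +
    ggplot2::facet_wrap(~temperature_C, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL,
                  y = expression(P[e] ~ (10^-3 ~ cm %.% min^-1))) +
    bar_theme()
}

#' @describeIn decompose_conditions Stacked paracellular / transcellular
#'   Pe components per condition.
#' @param object A `decomposition_summary`.
#' @param ... Unused.
#' @export
autoplot.decomposition_summary <- function(object, ...) {
  long <- object |>
    dplyr::select("condition_id", Paracellular = "pe_paracellular_scaled",
                  Transcellular = "pe_transcellular_scaled") |>
    tidyr::pivot_longer(-"condition_id", names_to = "pathway",
                        values_to = "pe_scaled")
  ggplot2::ggplot(long, ggplot2::aes(.data$condition_id, .data$pe_scaled,
                                     fill = .data$pathway)) +
    ggplot2::geom_col(colour = "black") +
    ggplot2::scale_fill_grey(start = 0.85, end = 0.5) +
    ggplot2::labs(x = NULL, fill = NULL,
                  y = expression(P[e] ~ (10^-3 ~ cm %.% min^-1))) +
    bar_theme()
}

#' @describeIn analyze_transport Transcytosis quotient per condition,
#'   mean +/- SEM, faceted by direction.
#' @param object A `transport_summary`.
#' @param ... Unused.
#' @export
autoplot.transport_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$condition_id,
                                       .data$quotient_mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$quotient_mean - .data$quotient_sem,
      ymax = .data$quotient_mean + .data$quotient_sem), width = 0.25) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = NULL, y = "Transcytosis quotient") +
    bar_theme()
}

#' @describeIn analyze_qpcr Percent-of-control expression per gene and
#'   condition with a 100 % reference line.
#' @param object A `qpcr_summary`.
#' @param ... Unused.
#' @export
autoplot.qpcr_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$gene,
                                       .data$pct_of_control_mean,
                                       fill = .data$condition_id)) +
    ggplot2::geom_col(position = "dodge", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$pct_of_control_mean - .data$pct_of_control_sem,
      ymax = .data$pct_of_control_mean + .data$pct_of_control_sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::scale_fill_grey(start = 0.9, end = 0.4) +
    ggplot2::labs(x = NULL, y = "mRNA level (% of control)", fill = NULL) +
    bar_theme()
}

#' @describeIn analyze_mtt Viability per condition, mean +/- SEM.
#' @param object An `mtt_summary`.
#' @param ... Unused.
#' @export
autoplot.mtt_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$condition_id,
                                       .data$viability_mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$viability_mean - .data$viability_sem,
      ymax = .data$viability_mean + .data$viability_sem), width = 0.25) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Relative viability (%)") +
    bar_theme()
}
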