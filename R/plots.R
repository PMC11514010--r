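# Plots -------------------------------------------------------------------

#' Plot the decay-channel competition of a yield table
#'
#' Stacked branching fractions (fluorescence, intersystem crossing,
#' internal conversion) per emitter — a visual version of the quantum
#' yield competition QYF = k_r / (k_r + k_ISC + k_IC).
#'
#' @param tab A [yield_table()] tibble.
#' @return A ggplot.
#' @export
plot_yield_channels <- function(tab) {
  long <- tidyr::pivot_longer(
    tab[c("name", "qyf", "phi_isc", "phi_ic")],
    cols = c("qyf", "phi_isc", "phi_ic"),
    names_to = "channel", values_to = "fraction"
  )
  long$channel <- factor(
    long$channel, levels = c("phi_ic", "phi_isc", "qyf"),
    labels = c("internal conversion", "intersystem crossing", "fluorescence")
  )
  long$name <- factor(long$name, levels = unique(tab$name))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$fraction,
                                     fill = .data$channel)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = NULL, y = "Branching fraction", fill = "Channel") +
    ggplot2::theme_minimal()
}

#' Plot a calibrated FCWD against the rate points it was fitted to
#'
#' Shows the gap dependence of k_ISC / SOCME^2 implied by the fitted
#' Franck-Condon weighted density of states together with the observed
#' points — the energy-gap-law view of the calibration.
#'
#' @param object An `fcwd_fit` from [calibrate_fcwd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcwd_fit
#' @export
autoplot.fcwd_fit <- function(object, ...) {
  pts <- object$points
  gap_grid <- seq(min(pts$gap) * 0.8, max(pts$gap) * 1.2, length.out = 200)
  curve <- tibble(
    gap = gap_grid,
    k_per_v2 = isc_rate(1, gap_grid, object$params)
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$gap, y = .data$k_per_v2)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(
      data = dplyr::mutate(pts, k_per_v2 = .data$k_isc / .data$socme^2),
      size = 2
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "S1-T1 gap (eV)",
                  y = expression(k[ISC] / SOCME^2 ~ (s^-1 ~ cm^2))) +
    ggplot2::theme_minimal()
}
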