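# ggplot2 visualisations for each result type.

#' Plot a force-extension cycle
#'
#' Stretch in red, relax in blue, the conventional rendering of
#' pull-relax cycles.
#'
#' @param traces Long trace tibble (as in `fec_experiment$traces`).
#' @param molecule,cycle Which cycle to draw (defaults to the first).
#' @return A ggplot object.
#' @export
plot_fec <- function(traces, molecule = NULL, cycle = NULL) {
  if (inherits(traces, "fec_experiment")) traces <- traces$traces
  molecule <- molecule %||% traces$molecule[1]
  cycle <- cycle %||% min(traces$cycle[traces$molecule == molecule])
  dat <- filter(traces, .data$molecule == !!molecule, .data$cycle == !!cycle)
  ggplot2::ggplot(dat, ggplot2::aes(.data$extension_nm, .data$force_pN,
                                    colour = .data$sweep)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(stretch = "#c0392b", relax = "#2e6da4")) +
    ggplot2::labs(x = "Extension (nm)", y = "Force (pN)",
                  title = sprintf("Molecule %s, cycle %s", molecule, cycle)) +
    ggplot2::theme_minimal()
}

#' @method autoplot dlc_distribution
#' @export
autoplot.dlc_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$bin_center, .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$peak_location_nm,
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::labs(x = expression(Delta * L[c] ~ "(nm)"), y = "Cycles",
                  subtitle = sprintf("peak %.1f nm, n = %d",
                                     object$peak_location_nm, object$n)) +
    ggplot2::theme_minimal()
}

#' @method autoplot tm_fit
#' @export
autoplot.tm_fit <- function(object, ...) {
  ggplot2::ggplot(object$derivative,
                  ggplot2::aes(.data$temperature_C, .data$dfir)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm_C, linetype = "dashed",
                        colour = "#c0392b") +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "d(I350/I330)/dT (1/°C)",
                  subtitle = sprintf("Tm = %.2f °C", object$tm_C)) +
    ggplot2::theme_minimal()
}

#' @method autoplot fp_fit
#' @export
autoplot.fp_fit <- function(object, ...) {
  curve <- tibble(
    conc_uM = 10^seq(log10(max(min(object$data$conc_uM[object$data$conc_uM > 0]),
                                1e-3)),
                     log10(max(object$data$conc_uM)), length.out = 200))
  curve$p_mP <- object$pmax * curve$conc_uM / (object$kd_uM + curve$conc_uM)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc_uM, .data$p_mP)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "#2e6da4") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (µM)", y = "Polarization",
                  subtitle = sprintf("Kd = %.2f µM", object$kd_uM)) +
    ggplot2::theme_minimal()
}

#' Box plot of force distributions by condition
#'
#' Whiskers at the 10th/90th percentiles, box at the interquartile range,
#' line at the median, point at the mean.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the value and grouping
#'   variables.
#' @return A ggplot object.
#' @export
plot_force_box <- function(data, value, group) {
  stats <- data %>%
    group_by(.data[[group]]) %>%
    summarise(box_stats(.data[[value]]), .groups = "drop")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data[[group]])) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                           width = 0.2) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(factor(.data[[group]])) - 0.25,
      xmax = as.numeric(factor(.data[[group]])) + 0.25,
      ymin = .data$p25, ymax = .data$p75), fill = "grey85", colour = "grey20") +
    ggplot2::geom_segment(ggplot2::aes(
      x = as.numeric(factor(.data[[group]])) - 0.25,
      xend = as.numeric(factor(.data[[group]])) + 0.25,
      y = .data$median, yend = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 15, size = 2) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
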