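# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy fp_fit
#' @export
tidy.fp_fit <- function(x, ...) {
  tibble(term = c("pmax", "kd"),
         estimate = c(x$pmax, x$kd_uM),
         std.error = c(x$pmax_se, x$kd_se))
}

#' @method glance fp_fit
#' @export
glance.fp_fit <- function(x, ...) {
  tibble(kd_uM = x$kd_uM, pmax = x$pmax, residual_norm = x$residual_norm,
         background = x$background, nobs = x$n)
}

#' @method tidy tm_fit
#' @export
tidy.tm_fit <- function(x, ...) {
  tibble(term = "tm", estimate = x$tm_C)
}

#' @method glance tm_fit
#' @export
glance.tm_fit <- function(x, ...) {
  tibble(tm_C = x$tm_C, dfir_at_peak = x$dfir_at_peak,
         smooth_window = x$smooth_window,
         nobs = nrow(x$derivative))
}

#' @method tidy dlc_distribution
#' @export
tidy.dlc_distribution <- function(x, ...) {
  x$histogram
}

#' @method glance dlc_distribution
#' @export
glance.dlc_distribution <- function(x, ...) {
  tibble(peak_location_nm = x$peak_location_nm, peak_sd_nm = x$peak_sd_nm,
         zero_peak_mass = x$zero_peak_mass, nobs = x$n)
}

#' @method tidy fec_analysis
#' @export
tidy.fec_analysis <- function(x, ...) {
  x$cycles
}

#' @method glance fec_analysis
#' @export
glance.fec_analysis <- function(x, ...) {
  cyc <- x$cycles[!is.na(x$cycles$label), ]
  tibble(n_cycles = nrow(x$cycles),
         n_transitions = nrow(x$transitions),
         frac_full = mean(cyc$label == "full"),
         frac_misfolded = mean(cyc$label == "misfolded"),
         frac_locked = mean(cyc$label == "locked"))
}

#' @method glance rate_calibration
#' @export
glance.rate_calibration <- function(x, ...) {
  tibble(unfold_rate0 = x$unfold_rate0,
         achieved_mean_force = x$achieved_mean_force,
         target_mean_force = x$target_mean_force,
         iterations = x$iterations, n_cycles = x$n_cycles)
}
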