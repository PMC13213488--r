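# Ensemble binding assays: nanoDSF melting-temperature extraction from the
# 350/330 nm intrinsic-fluorescence ratio, and one-site fluorescence-
# polarization binding fits, each with a synthetic generator for testing.

#' Generate a synthetic two-state nanoDSF melt curve
#'
#' The fluorescence ratio I350/I330 follows a linear baseline plus a logistic
#' two-state transition,
#' \eqn{r(T) = b_0 + b_1 T + A / (1 + e^{-(T - T_m)/w})},
#' sampled on a temperature grid emulating a 20--90 degC thermal ramp.  The
#' 330 nm channel is a slowly decaying intensity and I350 is reconstructed as
#' ratio times I330; Gaussian noise of sd `noise_sd` (ratio units) is applied
#' to the ratio before reconstruction.
#'
#' @param tm Transition midpoint (degC); must lie inside the grid.
#' @param width Logistic width `w` in degC.
#' @param amplitude Ratio change `A` across the transition.
#' @param baseline Length-2 numeric: intercept and slope (per degC) of the
#'   pre-transition ratio baseline.
#' @param noise_sd Gaussian noise sd on the ratio.
#' @param t_min,t_max,t_step Temperature grid in degC.
#' @param seed Optional seed.
#' @return A tibble of class `melt_curve`: `temperature_C`, `int330`,
#'   `int350`, with the generating truth in `attr(, "truth")`.
#' @export
generate_melt <- function(tm = 52.7, width = 2, amplitude = 0.3,
                          baseline = c(0.85, 0.0005), noise_sd = 0,
                          t_min = 20, t_max = 90, t_step = 0.1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (tm <= t_min || tm >= t_max) stop_invalid("`tm` must lie inside the temperature grid.")
  temp <- seq(t_min, t_max, by = t_step)
  ratio <- baseline[1] + baseline[2] * temp +
    amplitude / (1 + exp(-(temp - tm) / width))
  if (noise_sd > 0) ratio <- ratio + rnorm(length(temp), 0, noise_sd)
  int330 <- 5000 * (1 - 0.002 * (temp - t_min))
  out <- tibble(temperature_C = temp, int330 = int330,
                int350 = ratio * int330)
  attr(out, "truth") <- list(tm = tm, width = width, amplitude = amplitude,
                             baseline = baseline, noise_sd = noise_sd)
  class(out) <- c("melt_curve", class(out))
  out
}

#' First derivative of the smoothed fluorescence ratio
#'
#' Computes the 350/330 nm intensity ratio, smooths it by local quadratic
#' regression (Savitzky--Golay, window `smooth_window` points) and
#' differentiates it on the temperature grid by central differences.  The
#' extremum of this derivative marks the melting temperature.
#'
#' @param curve Data frame with `temperature_C`, `int330`, `int350`
#'   (at least 20 points, strictly increasing temperature).
#' @param smooth_window Odd window length, smaller than half the series.
#' @return A tibble: `temperature_C`, `dfir` (derivative of the fluorescence
#'   intensity ratio, 1/degC).
#' @export
melt_ratio_derivative <- function(curve, smooth_window = 7) {
  need <- c("temperature_C", "int330", "int350")
  if (!is.data.frame(curve) || !all(need %in% names(curve))) {
    stop_invalid("`curve` must have columns temperature_C, int330, int350.")
  }
  n <- nrow(curve)
  if (n < 20) stop_invalid("`curve` needs at least 20 points.")
  if (any(diff(curve$temperature_C) <= 0)) {
    stop_invalid("`temperature_C` must be strictly increasing.")
  }
  if (any(curve$int330 <= 0)) {
    abort("`int330` contains non-positive intensities; ratio undefined.",
          class = "ripfit_invalid_curve")
  }
  if (smooth_window %% 2 == 0 || smooth_window >= n / 2 || smooth_window < 3) {
    stop_invalid("`smooth_window` must be odd, >= 3 and < n/2.")
  }
  ratio <- curve$int350 / curve$int330
  smooth <- signal::sgolayfilt(ratio, p = 2, n = smooth_window)
  temp <- curve$temperature_C
  dfir <- numeric(n)
  dfir[2:(n - 1)] <- (smooth[3:n] - smooth[1:(n - 2)]) / (temp[3:n] - temp[1:(n - 2)])
  dfir[1] <- (smooth[2] - smooth[1]) / (temp[2] - temp[1])
  dfir[n] <- (smooth[n] - smooth[n - 1]) / (temp[n] - temp[n - 1])
  tibble(temperature_C = temp, dfir = dfir)
}

#' Melting temperature from a ratio-derivative series
#'
#' The melting temperature is the temperature of the global extremum of the
#' ratio derivative (the transition inflection point), refined by quadratic
#' interpolation of the three neighbouring grid points.  The extremum of
#' largest magnitude is used, so the result does not depend on whether the
#' instrument's plotted derivative is negated; the signed derivative value at
#' the extremum is returned as an attribute.
#'
#' @param derivative A tibble from [melt_ratio_derivative()].
#' @param min_amplitude Minimum derivative magnitude (1/degC) below which
#'   the series is declared flat (no transition).
#' @return The melting temperature in degC (numeric scalar), with attributes
#'   `dfir` (signed derivative at the extremum) and `sign`.
#' @export
extract_tm <- function(derivative, min_amplitude = 1e-4) {
  if (!is.data.frame(derivative) || !all(c("temperature_C", "dfir") %in% names(derivative))) {
    stop_invalid("`derivative` must have columns temperature_C and dfir.")
  }
  d <- derivative$dfir
  temp <- derivative$temperature_C
  # ignore the one-sided edge estimates when locating the extremum
  interior <- 2:(length(d) - 1L)
  i <- interior[which.max(abs(d[interior]))]
  # flat means no localized extremum: a constant nonzero derivative (a
  # sloping baseline with no transition) is just as transition-free as zero
  if (max(abs(d[interior] - median(d[interior]))) < min_amplitude) {
    abort("derivative series is flat: no melting transition found.",
          class = "ripfit_no_transition")
  }
  tm <- temp[i]
  y0 <- abs(d[i - 1L]); y1 <- abs(d[i]); y2 <- abs(d[i + 1L])
  denom <- y0 - 2 * y1 + y2
  if (denom < 0) {
    tm <- temp[i] + 0.5 * (temp[i + 1L] - temp[i]) * (y0 - y2) / denom
  }
  structure(tm, dfir = d[i], sign = sign(d[i]))
}

#' Fit a melting temperature to a nanoDSF curve
#'
#' Convenience wrapper chaining [melt_ratio_derivative()] and
#' [extract_tm()]; keeps the derivative series for plotting.
#'
#' @inheritParams melt_ratio_derivative
#' @inheritParams extract_tm
#' @return An object of class `tm_fit` with elements `tm_C`, `derivative`,
#'   `smooth_window`, `dfir_at_peak`.
#' @export
fit_tm <- function(curve, smooth_window = 7, min_amplitude = 1e-4) {
  deriv <- melt_ratio_derivative(curve, smooth_window = smooth_window)
  tm <- extract_tm(deriv, min_amplitude = min_amplitude)
  structure(list(tm_C = as.numeric(tm), derivative = deriv,
                 smooth_window = smooth_window,
                 dfir_at_peak = attr(tm, "dfir")),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> Tm = %.2f degC (dFIR at extremum %.3g / degC)\n",
              x$tm_C, x$dfir_at_peak))
  invisible(x)
}

#' Fluorescence polarization from channel intensities
#'
#' \eqn{P = (I_\parallel - I_\perp) / (I_\parallel + I_\perp)}, bounded in
#' \eqn{[-1, 1]} for non-negative intensities; multiplied by 1000 when
#' millipolarization units are requested.
#'
#' @param i_parallel,i_perpendicular Non-negative intensities (vectorised);
#'   a pair that is both zero is an error.
#' @param millipolarization Return mP instead of dimensionless P.
#' @return Polarization values.
#' @export
polarization <- function(i_parallel, i_perpendicular, millipolarization = FALSE) {
  if (any(i_parallel < 0) || any(i_perpendicular < 0)) {
    stop_invalid("intensities must be non-negative.")
  }
  tot <- i_parallel + i_perpendicular
  if (any(tot == 0)) {
    abort("polarization undefined: both intensities are zero.",
          class = "ripfit_undefined_polarization")
  }
  p <- (i_parallel - i_perpendicular) / tot
  if (millipolarization) p * 1000 else p
}

#' Generate a synthetic fluorescence-polarization titration
#'
#' Forward model of the one-site binding isotherm
#' \eqn{P = P_{max} C / (K_d + C)} with optional Gaussian noise and
#' replicates, emulating a titration of protein (0--80 uM) into a fixed
#' ligand concentration.
#'
#' @param kd Dissociation constant in uM (> 0).
#' @param pmax Plateau polarization (units carried through, typically mP).
#' @param concentrations Protein concentrations in uM; the default is 12
#'   log-spaced points over 0.1--80 uM plus a zero-concentration control.
#' @param noise_sd Gaussian noise sd (same units as `pmax`).
#' @param n_replicates Replicate measurements per concentration.
#' @param seed Optional seed.
#' @return A tibble of class `fp_titration`: `conc_uM`, `replicate`, `p_mP`,
#'   with the generating truth in `attr(, "truth")`.
#' @export
generate_fp <- function(kd = 4.7, pmax = 100,
                        concentrations = NULL, noise_sd = 0,
                        n_replicates = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_number(kd, "kd", min = 0, allow_zero = FALSE)
  concentrations <- concentrations %||%
    c(0, 10^seq(log10(0.1), log10(80), length.out = 12))
  if (any(concentrations < 0)) stop_invalid("concentrations must be >= 0.")
  grid <- tidyr::expand_grid(conc_uM = concentrations,
                             replicate = seq_len(n_replicates))
  p <- pmax * grid$conc_uM / (kd + grid$conc_uM)
  if (noise_sd > 0) p <- p + rnorm(length(p), 0, noise_sd)
  out <- tibble(conc_uM = grid$conc_uM, replicate = grid$replicate, p_mP = p)
  attr(out, "truth") <- list(kd = kd, pmax = pmax, noise_sd = noise_sd)
  class(out) <- c("fp_titration", class(out))
  out
}

#' One-site binding fit to a fluorescence-polarization titration
#'
#' Nonlinear least squares for the one-site isotherm
#' \eqn{P = P_{max} C / (K_d + C)} (Levenberg--Marquardt), with standard
#' errors from the fit curvature.  Zero-concentration wells serve as
#' background controls: their mean polarization is subtracted from all
#' points before fitting.
#'
#' @param titration Data frame with `conc_uM` and `p_mP` (replicate rows
#'   allowed); at least 5 distinct concentrations spanning at least one
#'   decade.
#' @param background Optional explicit background polarization; default uses
#'   the zero-concentration wells (0 if absent).
#' @return An object of class `fp_fit`: `kd_uM`, `pmax`, `kd_se`, `pmax_se`,
#'   `residual_norm`, `n`, `background`, `data` (background-subtracted) and
#'   the underlying `nls` object in `$fit`.
#' @export
fit_one_site <- function(titration, background = NULL) {
  if (!is.data.frame(titration) ||
      !all(c("conc_uM", "p_mP") %in% names(titration))) {
    stop_invalid("`titration` must have columns `conc_uM` and `p_mP`.")
  }
  conc <- titration$conc_uM
  pos <- unique(conc[conc > 0])
  if (length(pos) < 5) stop_invalid("at least 5 nonzero concentrations required.")
  if (max(pos) / min(pos) < 10) {
    stop_invalid("concentrations must span at least one decade.")
  }
  background <- background %||%
    if (any(conc == 0)) mean(titration$p_mP[conc == 0]) else 0
  dat <- tibble(conc_uM = conc, p_mP = titration$p_mP - background)
  pmax0 <- max(dat$p_mP)
  kd0 <- {
    half <- pmax0 / 2
    above <- dat$conc_uM[dat$p_mP >= half & dat$conc_uM > 0]
    if (length(above)) min(above) else median(pos)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p_mP ~ pmax * conc_uM / (kd + conc_uM),
      data = dat,
      start = list(pmax = pmax0, kd = kd0),
      lower = c(pmax = 1e-9, kd = 1e-9),
      upper = c(pmax = Inf, kd = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("one-site fit failed: ", conditionMessage(e)),
                              class = "ripfit_fit_error")
  )
  est <- coef(fit)
  if (est["kd"] <= 2e-9 || est["kd"] >= 9e5) {
    abort(sprintf("one-site fit hit the Kd bound (%.3g uM).", est["kd"]),
          class = "ripfit_fit_error")
  }
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(pmax = NA, kd = NA))
  structure(list(kd_uM = unname(est["kd"]), pmax = unname(est["pmax"]),
                 kd_se = unname(se["kd"]), pmax_se = unname(se["pmax"]),
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 n = nrow(dat), background = background,
                 data = dat, fit = fit),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("<fp_fit> Kd = %.3g +/- %.2g uM, Pmax = %.3g +/- %.2g (n = %d)\n",
              x$kd_uM, x$kd_se, x$pmax, x$pmax_se, x$n))
  invisible(x)
}
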