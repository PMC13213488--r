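# Cycle classification (full / misfolded / locked), contour-length-change
# distributions with peak estimates, and the summary statistics used to
# compare conditions.

#' Classify one stretch-relax cycle
#'
#' Rules, applied in order on cycles from valid tethers:
#' * `locked` -- no transition of at least `min_size` nm in either sweep
#'   *and* the stretch starts from the unfolded state (first-branch fitted
#'   contour length of at least half the expected value).  The start-state
#'   condition separates a molecule genuinely trapped in the unfolded state
#'   from a folded record whose rips were merely too small to resolve;
#' * `full` -- total contour-length change of at least
#'   `full_frac * expected_dlc`;
#' * `misfolded` -- total change below that threshold even though the
#'   molecule was loaded to at least `misfold_force` pN (a state that cannot
#'   be unfolded at high force);
#' * `unclassified` otherwise (e.g. an incomplete pull that never reached
#'   high force).
#'
#' Locked and misfolded are mutually exclusive by construction: the locked
#' rule fires first.  Cycles from invalid tethers get `NA` and are excluded
#' from downstream tallies.  All arguments are vectorised.
#'
#' @param total_dlc Total contour-length change of the cycle in nm.
#' @param max_force Maximum force applied during the stretch in pN.
#' @param n_transitions Number of detected transitions (both sweeps) of at
#'   least the minimum rip size.
#' @param tether_status `"valid"`, `"multi_tether"` or `"broken"` from
#'   [validate_tether()].
#' @param expected_dlc Expected full-unfolding contour gain in nm.
#' @param full_frac Fraction of `expected_dlc` required for `full`.
#' @param misfold_force Minimum applied force for the misfold call, pN.
#' @param first_lc Fitted contour length of the first stretch branch in nm
#'   (`NA` disables the locked start-state condition).
#' @return A character vector of labels.
#' @export
classify_cycle <- function(total_dlc, max_force, n_transitions, tether_status,
                           expected_dlc, full_frac = 0.9, misfold_force = 20,
                           first_lc = NA_real_) {
  n <- max(length(total_dlc), length(max_force), length(n_transitions),
           length(tether_status))
  total_dlc <- rep_len(total_dlc, n)
  max_force <- rep_len(max_force, n)
  n_transitions <- rep_len(n_transitions, n)
  tether_status <- rep_len(tether_status, n)
  first_lc <- rep_len(first_lc, n)
  out <- rep(NA_character_, n)
  valid <- tether_status == "valid"
  starts_unfolded <- is.na(first_lc) | first_lc >= 0.5 * expected_dlc
  out[valid & n_transitions == 0 & starts_unfolded] <- "locked"
  todo <- valid & is.na(out)
  out[todo & !is.na(total_dlc) & total_dlc >= full_frac * expected_dlc] <- "full"
  out[todo & is.na(out) & !is.na(total_dlc) &
        total_dlc < full_frac * expected_dlc &
        max_force >= misfold_force] <- "misfolded"
  out[valid & is.na(out)] <- "unclassified"
  out
}

#' Contour-length-change distribution and peak estimate
#'
#' Histograms the per-cycle total contour-length changes (locked cycles
#' contribute at 0 nm) on bins of width `bin_width` centred on multiples of
#' the bin width, and locates the dominant peak by quadratic interpolation of
#' the three bins around the modal bin -- robust at the small cycle counts
#' (~20-30) typical of single-molecule datasets.
#'
#' @param cycles A data frame with `total_dlc_nm` and optionally `label`
#'   (from [analyze_cycles()]; rows with `NA` labels are dropped).  At least
#'   10 classified cycles are required.
#' @param bin_width Histogram bin width in nm.
#' @return A list of class `dlc_distribution`: `histogram` (tibble with
#'   `bin_left`, `bin_right`, `bin_center`, `count`), `peak_location_nm`,
#'   `peak_sd_nm` (sd of the values within two bins of the peak),
#'   `fraction_by_class` (tibble), `zero_peak_mass` (fraction of cycles in
#'   bins within one bin width of 0 nm) and `n`.
#' @export
delta_lc_distribution <- function(cycles, bin_width = 5) {
  if (!is.data.frame(cycles) || !"total_dlc_nm" %in% names(cycles)) {
    stop_invalid("`cycles` must be a data frame with a `total_dlc_nm` column.")
  }
  if (!"label" %in% names(cycles)) cycles$label <- "full"
  cycles <- cycles[!is.na(cycles$label), , drop = FALSE]
  if (nrow(cycles) < 10) {
    stop_invalid("at least 10 classified cycles are required.")
  }
  vals <- cycles$total_dlc_nm
  vals[cycles$label == "locked"] <- 0
  vals[is.na(vals)] <- 0
  lo <- floor(min(vals) / bin_width) - 1L
  hi <- ceiling(max(vals) / bin_width) + 1L
  breaks <- (seq(lo, hi) - 0.5) * bin_width
  counts <- as.integer(table(cut(vals, breaks = breaks, right = FALSE)))
  centers <- (seq(lo, hi - 1L)) * bin_width
  histogram <- tibble(bin_left = head(breaks, -1L), bin_right = tail(breaks, -1L),
                      bin_center = centers, count = counts)
  i_mode <- which.max(counts)
  peak <- centers[i_mode]
  if (i_mode > 1 && i_mode < length(counts)) {
    cl <- counts[i_mode - 1L]; cm <- counts[i_mode]; cr <- counts[i_mode + 1L]
    denom <- cl - 2 * cm + cr
    if (denom < 0) peak <- centers[i_mode] + 0.5 * bin_width * (cl - cr) / denom
  }
  near <- abs(vals - peak) <= 2 * bin_width
  peak_sd <- if (sum(near) > 1) sd(vals[near]) else 0
  fractions <- cycles %>%
    dplyr::count(.data$label) %>%
    mutate(fraction = .data$n / sum(.data$n))
  zero_mass <- mean(abs(vals) <= bin_width)
  structure(list(histogram = histogram,
                 peak_location_nm = peak,
                 peak_sd_nm = peak_sd,
                 fraction_by_class = fractions,
                 zero_peak_mass = zero_mass,
                 bin_width = bin_width,
                 n = nrow(cycles),
                 values = vals),
            class = "dlc_distribution")
}

#' @export
print.dlc_distribution <- function(x, ...) {
  cat(sprintf(
    "<dlc_distribution> n = %d, peak %.1f nm (sd %.1f), zero-peak mass %.1f%%\n",
    x$n, x$peak_location_nm, x$peak_sd_nm, 100 * x$zero_peak_mass))
  print(x$fraction_by_class)
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-sample t-test assuming unequal variances (Welch--Satterthwaite
#' degrees of freedom), the convention for comparing force distributions
#' between conditions.  A thin tidy wrapper around [stats::t.test()].
#'
#' @param sample_a,sample_b Numeric vectors, each with at least two values
#'   and nonzero variance.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_invalid("each sample needs at least two observations.")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    stop_invalid("both samples have zero variance; the Welch statistic is undefined.")
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Box-plot order statistics
#'
#' The six statistics drawn in the box-plot convention used for force
#' distributions: whiskers at the 10th and 90th percentiles, box at the
#' interquartile range, inner line at the median, inner square at the mean.
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param sample Numeric vector with at least 5 values.
#' @return A one-row tibble: `p10`, `p25`, `median`, `mean`, `p75`, `p90`.
#' @export
box_stats <- function(sample) {
  if (length(sample) < 5) stop_invalid("`sample` needs at least 5 values.")
  q <- quantile(sample, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  tibble(p10 = q[1], p25 = q[2], median = q[3], mean = mean(sample),
         p75 = q[4], p90 = q[5])
}
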