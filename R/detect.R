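# Detection of unfolding/refolding rips in force-extension sweeps, rip-force
# quantification, and single-tether validation.

#' Detect unfolding/refolding transitions in one sweep
#'
#' Rips are located on the extension signal: the per-sample extension advance
#' is compared against a running-median elastic baseline, and samples whose
#' residual advance exceeds 5x its median absolute deviation (with a floor of
#' `min_size / 4` to keep noiseless sweeps clean) are flagged.  Neighbouring
#' candidates separated by fewer than `merge_gap` samples are merged -- block
#' averaging of the raw signal can spread one rip over two output samples --
#' and the merged extension jump must reach `min_size` nm to be reported.
#' An extension gain is an unfolding rip, an extension loss a refolding rip;
#' candidates whose force change has the wrong sign (force must drop across
#' an unfolding rip and rise across a refolding one) are discarded.
#'
#' @param trace A data frame with columns `time_s`, `extension_nm`,
#'   `force_pN` for a single monotone sweep (at least 50 samples).
#' @param min_size Minimum extension jump in nm (default 10).
#' @param merge_gap Candidate runs closer than this many samples are merged.
#' @param mad_mult Threshold multiplier on the MAD of the residual advance.
#' @param window Averaging window (s) passed to [transition_force()].
#' @return A tibble with one row per transition: `direction`, `onset_index`
#'   (last pre-rip sample), `end_index` (first post-rip sample),
#'   `extension_jump_nm` (signed), `force_before_pN`,
#'   `preceding_branch`, `following_branch`.
#' @export
detect_transitions <- function(trace, min_size = 10, merge_gap = 3,
                               mad_mult = 5, window = 0.05) {
  check_trace(trace)
  x <- trace$extension_nm
  d <- diff(x)
  k <- min(21L, 2L * floor((length(d) - 1L) / 2L) + 1L)
  baseline <- runmed(d, k, endrule = "median")
  resid <- d - baseline
  thr <- max(mad_mult * mad(resid), min_size / 4)
  cand <- which(abs(resid) > thr)
  out <- empty_transitions()
  if (length(cand)) {
    grp <- cumsum(c(1L, diff(cand) >= merge_gap))
    runs <- split(cand, grp)
    rows <- lapply(runs, function(idx) {
      # widen by one sample each side: block averaging can smear part of a
      # rip into a neighbouring sample that stays under the point threshold
      i1 <- max(1L, min(idx) - 1L)
      i2 <- min(length(d), max(idx) + 1L)
      # size from the extension levels across the run, net of the elastic
      # advance: unbiased however the rip splits across output samples
      jump <- (x[i2 + 1L] - x[i1]) - baseline[min(idx)] * (i2 + 1L - i1)
      tibble(onset_index = i1, end_index = i2 + 1L, extension_jump_nm = jump)
    })
    out <- bind_rows(rows)
    # force-sign consistency: unfolds release force, refolds regain it
    df <- trace$force_pN[out$end_index] - trace$force_pN[out$onset_index]
    keep <- abs(out$extension_jump_nm) >= min_size & df * out$extension_jump_nm <= 0
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty_transitions())
  out <- out %>%
    arrange(.data$onset_index) %>%
    mutate(direction = ifelse(.data$extension_jump_nm > 0, "unfold", "refold"),
           preceding_branch = row_number(),
           following_branch = row_number() + 1L)
  out$force_before_pN <- transition_force(trace, out, window = window)
  out[, c("direction", "onset_index", "end_index", "extension_jump_nm",
          "force_before_pN", "preceding_branch", "following_branch")]
}

empty_transitions <- function() {
  tibble(direction = character(), onset_index = integer(),
         end_index = integer(), extension_jump_nm = numeric(),
         force_before_pN = numeric(), preceding_branch = integer(),
         following_branch = integer())
}

check_trace <- function(trace) {
  need <- c("time_s", "extension_nm", "force_pN")
  if (!is.data.frame(trace) || !all(need %in% names(trace))) {
    abort(paste0("`trace` must be a data frame with columns ",
                 paste(need, collapse = ", ")),
          class = "ripfit_invalid_trace")
  }
  if (nrow(trace) < 50L) {
    abort("`trace` must contain at least 50 samples.",
          class = "ripfit_invalid_trace")
  }
  if (any(diff(trace$time_s) <= 0)) {
    abort("`trace` time stamps must be strictly increasing.",
          class = "ripfit_invalid_trace")
  }
  invisible(trace)
}

#' Average force immediately before a transition
#'
#' The rip force is the arithmetic mean of the force samples in the `window`
#' seconds immediately preceding the jump onset, the windowed-average
#' estimator conventionally applied to 100 Hz data.  If the preceding branch
#' is shorter than the window (e.g. two rips in quick succession) the window
#' shrinks to the available samples and a warning is logged.
#'
#' @param trace The sweep the transitions were detected in.
#' @param transitions A tibble from [detect_transitions()] (or any data frame
#'   with an `onset_index` column); vectorised over rows.
#' @param window Averaging window in s (default 0.05, i.e. 5 samples at
#'   100 Hz).
#' @return A numeric vector of forces in pN, one per transition.
#' @export
transition_force <- function(trace, transitions, window = 0.05) {
  check_trace(trace)
  if (nrow(transitions) == 0) return(numeric(0))
  dt <- median(diff(trace$time_s))
  nw <- max(1L, round(window / dt))
  onset <- transitions$onset_index
  prev_end <- c(1L, head(transitions$end_index, -1L))
  vapply(seq_along(onset), function(j) {
    lo <- max(prev_end[j], onset[j] - nw + 1L)
    if (onset[j] - lo + 1L < nw) {
      warn(sprintf(
        "pre-transition force window shrunk to %d sample(s) at index %d",
        onset[j] - lo + 1L, onset[j]),
        class = "ripfit_window_shrunk")
    }
    mean(trace$force_pN[lo:onset[j]])
  }, numeric(1))
}

#' Validate that a cycle comes from a single intact tether
#'
#' Two checks mirror standard single-tether screening: the total measured
#' unfolded length must not exceed the expected full-unfolding value by more
#' than `tolerance` (a doubled length is the signature of two tethers in
#' parallel), and any tether rupture -- the force collapsing to near zero
#' mid-sweep -- flags the record as broken.
#'
#' @param stretch The stretch sweep (data frame with `time_s`,
#'   `extension_nm`, `force_pN`).
#' @param transitions Transitions detected on the stretch sweep.
#' @param expected_total_dlc Expected full-unfolding contour gain in nm.
#' @param total_dlc Measured total contour-length change in nm (from branch
#'   fitting) if available; otherwise the summed unfolding extension jumps
#'   are used as a proxy.
#' @param tolerance Relative excess allowed over `expected_total_dlc`.
#' @param rupture_force Force level (pN) below which the tether counts as
#'   ruptured once the sweep has been loaded beyond `5 * rupture_force`.
#' @return One of `"valid"`, `"multi_tether"`, `"broken"`.
#' @export
validate_tether <- function(stretch, transitions, expected_total_dlc,
                            total_dlc = NULL, tolerance = 0.25,
                            rupture_force = 0.5) {
  check_trace(stretch)
  f <- stretch$force_pN
  i_max <- which.max(f)
  if (max(f) > 5 * rupture_force && i_max < length(f)) {
    after <- f[i_max:length(f)]
    n_tail <- max(5L, round(length(after) / 20))
    if (mean(tail(after, n_tail) < rupture_force) > 0.9) {
      return("broken")
    }
  }
  measured <- total_dlc %||% sum(transitions$extension_jump_nm[
    transitions$direction == "unfold"])
  if (isTRUE(measured > expected_total_dlc * (1 + tolerance))) {
    return("multi_tether")
  }
  "valid"
}
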