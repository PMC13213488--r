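# Branch-wise WLC fitting: each inter-transition branch is fitted with the
# series tether model (DNA handles + protein), with the net unfolded contour
# length as the only free parameter.  All polymer constants stay clamped.

#' Fit one force-extension branch with the series WLC model
#'
#' The model is the full tether: DNA handles (Lp 30 nm, K 500 pN, fixed),
#' unfolded polypeptide (Lp 0.5 nm, K 300 pN, fixed) and the folded core's
#' rigid span, which shrinks in proportion to the unfolded fraction.  The one
#' free parameter is the net unfolded contour length `Lc` (0 for the fully
#' folded branch, ~200 nm for the fully unfolded one).  The objective is the
#' force residual at the measured extensions -- force noise dominates 100 Hz
#' data -- minimised by golden-section search; the model force is evaluated
#' through a dense force grid, making each evaluation a single monotone
#' interpolation.
#'
#' @param segment Data frame with `extension_nm` and `force_pN` for one
#'   branch; at least 10 points spanning at least `min_span` pN.
#' @param constants A [wlc_constants()] object (the clamped parameters).
#' @param min_points,min_span Segment admissibility thresholds.
#' @param f_max,grid_n Force grid used to evaluate the model.
#' @param bounds Search interval for the net contour length (nm).  The lower
#'   bound sits slightly below zero so noise around the folded state does not
#'   pile fits onto a hard boundary.
#' @param robust Down-weight outlying force residuals by iteratively
#'   reweighted least squares with Tukey's bisquare (4 reweighting passes).
#'   This makes the fitted contour length that of the majority state of the
#'   branch, so transitions too small to be resolved by rip detection (which
#'   leave short foreign-state stretches inside a branch) do not drag the
#'   estimate.  Set to `FALSE` for plain least squares.
#' @return A one-row tibble (`branch_fit`): `fitted_lc_nm`, `residual_rms_pN`,
#'   `n_points`, `converged`, and the clamped constants echoed
#'   (`handle_lp`, `handle_lc`, `handle_k`, `protein_lp`, `protein_k`).
#'   Returns `NULL` (with a warning) for an inadmissible segment.
#' @export
fit_branch <- function(segment, constants = wlc_constants(),
                       min_points = 10L, min_span = 1,
                       f_max = 80, grid_n = 4001,
                       bounds = NULL, robust = TRUE) {
  if (!is.data.frame(segment) ||
      !all(c("extension_nm", "force_pN") %in% names(segment))) {
    stop_invalid("`segment` must have columns `extension_nm` and `force_pN`.")
  }
  if (nrow(segment) < min_points ||
      diff(range(segment$force_pN)) < min_span) {
    warn(sprintf("branch segment skipped: %d points spanning %.2f pN",
                 nrow(segment), diff(range(segment$force_pN))),
         class = "ripfit_short_branch")
    return(NULL)
  }
  bounds <- bounds %||% c(-0.15, 1.3) * constants$expected_dlc
  grid <- tether_grid(constants, f_max = f_max, n = grid_n)
  x <- segment$extension_nm
  f <- segment$force_pN
  model_force <- function(lc) {
    approx(grid$a + lc * grid$b, grid$force, xout = x, rule = 2)$y
  }
  w <- rep(1, length(x))
  ssr <- function(lc) sum(w * (f - model_force(lc))^2)
  opt <- optimize(ssr, interval = bounds, tol = 1e-4)
  if (robust) {
    for (it in seq_len(4L)) {
      r <- f - model_force(opt$minimum)
      scale <- max(mad(r), 0.05)   # floor keeps noiseless branches stable
      u <- r / (4.685 * scale)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w > 0) < min_points) break
      opt <- optimize(ssr, interval = bounds, tol = 1e-4)
    }
  }
  at_bound <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum) < 0.5
  if (at_bound) {
    abort(sprintf(
      "branch fit did not converge: contour length hit the search bound at %.1f nm (SSR %.3g)",
      opt$minimum, opt$objective),
      class = "ripfit_fit_error")
  }
  r_final <- f - model_force(opt$minimum)
  tibble(
    fitted_lc_nm = opt$minimum,
    residual_rms_pN = sqrt(mean(r_final^2)),
    n_points = nrow(segment),
    converged = TRUE,
    handle_lp = constants$handle_lp, handle_lc = constants$handle_lc,
    handle_k = constants$handle_k,
    protein_lp = constants$protein_lp, protein_k = constants$protein_k
  )
}

# Split a sweep into inter-transition branches, dropping `pad` samples on
# either side of each rip (jump contamination from block averaging).
branch_segments <- function(trace, transitions, pad = 3L) {
  n <- nrow(trace)
  if (nrow(transitions) == 0) {
    return(list(trace))
  }
  starts <- c(1L, transitions$end_index + pad)
  ends <- c(transitions$onset_index - pad, n)
  lapply(seq_along(starts), function(j) {
    if (starts[j] > ends[j]) return(trace[0, ])
    trace[starts[j]:ends[j], , drop = FALSE]
  })
}

# Fit every branch of one sweep; returns a tibble with branch ids (NULL rows
# for skipped branches are kept as NA fits so transitions stay indexable).
fit_sweep_branches <- function(trace, transitions, constants, grid = NULL,
                               pad = 3L) {
  segs <- branch_segments(trace, transitions, pad = pad)
  rows <- lapply(seq_along(segs), function(b) {
    ft <- tryCatch(
      suppressWarnings(fit_branch(segs[[b]], constants)),
      ripfit_fit_error = function(e) NULL
    )
    if (is.null(ft)) {
      ft <- tibble(fitted_lc_nm = NA_real_, residual_rms_pN = NA_real_,
                   n_points = nrow(segs[[b]]), converged = FALSE,
                   handle_lp = constants$handle_lp,
                   handle_lc = constants$handle_lc,
                   handle_k = constants$handle_k,
                   protein_lp = constants$protein_lp,
                   protein_k = constants$protein_k)
    }
    ft$branch <- b
    ft
  })
  bind_rows(rows) %>% select("branch", dplyr::everything())
}

#' Per-transition and total contour-length changes of one cycle
#'
#' Combines detected transitions with their flanking branch fits:
#' each transition's contour-length change is the fitted contour length of
#' the following branch minus that of the preceding branch, and the cycle
#' total is the last branch minus the first.
#'
#' @param transitions Transitions of one sweep (from [detect_transitions()]).
#' @param branch_fits Branch fits of the same sweep (tibble with `branch` and
#'   `fitted_lc_nm`, as from [fit_branch()] rows).
#' @return A list of class `cycle_result`: `transitions` (input plus
#'   `delta_lc_nm` and flanking fitted contour lengths), `branches`,
#'   `total_dlc_nm`, `partial` (`TRUE` when a missing branch fit left a
#'   transition without a contour change).
#' @export
cycle_delta_lc <- function(transitions, branch_fits) {
  lc <- branch_fits$fitted_lc_nm[order(branch_fits$branch)]
  k <- nrow(transitions)
  if (k > 0) {
    transitions$lc_before_nm <- lc[transitions$preceding_branch]
    transitions$lc_after_nm <- lc[transitions$following_branch]
    transitions$delta_lc_nm <- transitions$lc_after_nm - transitions$lc_before_nm
  } else {
    transitions$lc_before_nm <- numeric(0)
    transitions$lc_after_nm <- numeric(0)
    transitions$delta_lc_nm <- numeric(0)
  }
  total <- if (length(lc) >= 1 && !is.na(lc[length(lc)]) && !is.na(lc[1])) {
    lc[length(lc)] - lc[1]
  } else NA_real_
  partial <- anyNA(lc)
  if (partial) {
    warn("one or more branch fits missing; cycle result flagged partial",
         class = "ripfit_partial_cycle")
  }
  structure(list(transitions = transitions, branches = branch_fits,
                 total_dlc_nm = total, partial = partial),
            class = "cycle_result")
}

#' Analyse all cycles of an experiment: detect, fit, classify
#'
#' The end-to-end per-cycle analysis: rips are detected on each stretch and
#' relax sweep, inter-transition branches are fitted with the series WLC
#' model, contour-length changes are assembled, tethers validated, and each
#' cycle is classified as `full`, `misfolded`, `locked` or `unclassified`
#' (see [classify_cycle()]).
#'
#' @param x An `fec_experiment` from [simulate_experiment()], or a long trace
#'   tibble with `molecule`, `cycle`, `sweep` columns.
#' @param constants A [wlc_constants()] object.
#' @param min_size Minimum rip size in nm.
#' @param full_frac,misfold_force Classification thresholds, see
#'   [classify_cycle()].
#' @param head_force,tail_force Force bounds (pN) of the state-pure head and
#'   tail segments used for the cycle's start/end contour lengths: the head
#'   covers samples before the force first reaches `head_force` (initial
#'   state), the tail those above `tail_force` (final state, every
#'   unfoldable block unfolded, refolding suppressed).
#' @return A list of class `fec_analysis`: `cycles` (one row per cycle with
#'   `total_dlc_nm`, `max_force_pN`, counts, `tether_status`, `label`),
#'   `transitions` (all rips with `delta_lc_nm` and flanking contour
#'   lengths), `branches` (all branch fits), `constants`, `thresholds`.
#' @examples
#' cfg <- sim_config()
#' sim <- simulate_experiment(cfg, n_molecules = 1, n_cycles = 1, seed = 42)
#' an <- analyze_cycles(sim)
#' an$cycles
#' @export
analyze_cycles <- function(x, constants = wlc_constants(), min_size = 10,
                           full_frac = 0.9, misfold_force = 20,
                           head_force = 4, tail_force = 15) {
  traces <- if (inherits(x, "fec_experiment")) x$traces else x
  if (!all(c("molecule", "cycle", "sweep") %in% names(traces))) {
    stop_invalid("`x` must be an `fec_experiment` or a trace tibble with molecule/cycle/sweep columns.")
  }
  keys <- dplyr::distinct(traces, .data$molecule, .data$cycle)
  cyc_rows <- list(); tr_rows <- list(); br_rows <- list()
  for (i in seq_len(nrow(keys))) {
    m <- keys$molecule[i]; cy <- keys$cycle[i]
    stretch <- dplyr::filter(traces, .data$molecule == m, .data$cycle == cy,
                             .data$sweep == "stretch")
    relax <- dplyr::filter(traces, .data$molecule == m, .data$cycle == cy,
                           .data$sweep == "relax")
    tr_s <- detect_transitions(stretch, min_size = min_size)
    tr_r <- if (nrow(relax) >= 50) detect_transitions(relax, min_size = min_size)
            else empty_transitions()
    fits <- suppressWarnings(fit_sweep_branches(stretch, tr_s, constants))
    res <- suppressWarnings(cycle_delta_lc(tr_s, fits))
    if (nrow(relax) >= 50) {
      fits_r <- suppressWarnings(fit_sweep_branches(relax, tr_r, constants))
      res_r <- suppressWarnings(cycle_delta_lc(tr_r, fits_r))
    } else {
      fits_r <- fits[0, ]
      res_r <- NULL
    }
    status <- validate_tether(stretch, tr_s, constants$expected_dlc,
                              total_dlc = res$total_dlc_nm)
    # State-pure end-point estimates.  Head: samples before the force first
    # reaches head_force, i.e. before any plausible rip -- the initial state.
    # Tail: samples above tail_force, where every unfoldable block has long
    # since unfolded and refolding is suppressed -- the final state.  Their
    # difference gives a cycle total that transitions too small to detect
    # cannot contaminate.
    quiet_fit <- function(seg, min_span = 0.5) {
      if (nrow(seg) < 10) return(NA_real_)
      ft <- tryCatch(suppressWarnings(fit_branch(seg, constants,
                                                 min_span = min_span)),
                     ripfit_fit_error = function(e) NULL)
      if (is.null(ft)) NA_real_ else ft$fitted_lc_nm
    }
    start_lc <- quiet_fit(stretch[cummax(stretch$force_pN) < head_force, ])
    end_lc <- quiet_fit(stretch[stretch$force_pN > tail_force, ])
    n_rips <- nrow(tr_s) + nrow(tr_r)
    total <- if (!is.na(start_lc) && !is.na(end_lc)) {
      end_lc - start_lc
    } else res$total_dlc_nm
    if (n_rips == 0 && is.na(total)) total <- 0
    label <- classify_cycle(total, max(stretch$force_pN), n_rips, status,
                            expected_dlc = constants$expected_dlc,
                            full_frac = full_frac,
                            misfold_force = misfold_force,
                            first_lc = start_lc)
    cyc_rows[[i]] <- tibble(
      molecule = m, cycle = cy,
      n_unfold = sum(tr_s$direction == "unfold") + sum(tr_r$direction == "unfold"),
      n_refold = sum(tr_s$direction == "refold") + sum(tr_r$direction == "refold"),
      total_dlc_nm = total,
      max_force_pN = max(stretch$force_pN),
      first_lc_nm = if (nrow(fits)) fits$fitted_lc_nm[1] else NA_real_,
      last_lc_nm = if (nrow(fits)) fits$fitted_lc_nm[nrow(fits)] else NA_real_,
      start_lc_nm = start_lc,
      end_lc_nm = end_lc,
      partial = res$partial,
      tether_status = status,
      label = label
    )
    all_tr <- bind_rows(
      if (nrow(res$transitions)) mutate(res$transitions, sweep = "stretch"),
      if (!is.null(res_r) && nrow(res_r$transitions))
        mutate(res_r$transitions, sweep = "relax")
    )
    if (!is.null(all_tr) && nrow(all_tr)) {
      all_tr$molecule <- m; all_tr$cycle <- cy
      tr_rows[[length(tr_rows) + 1L]] <- all_tr
    }
    fits$sweep <- "stretch"
    if (nrow(fits_r)) fits_r$sweep <- "relax"
    fits_all <- bind_rows(fits, fits_r)
    fits_all$molecule <- m; fits_all$cycle <- cy
    br_rows[[length(br_rows) + 1L]] <- fits_all
  }
  structure(list(
    cycles = bind_rows(cyc_rows),
    transitions = if (length(tr_rows)) bind_rows(tr_rows) else
      mutate(empty_transitions(), sweep = character(), molecule = numeric(),
             cycle = integer()),
    branches = bind_rows(br_rows),
    constants = constants,
    thresholds = list(min_size = min_size, full_frac = full_frac,
                      misfold_force = misfold_force)
  ), class = "fec_analysis")
}

#' @export
print.fec_analysis <- function(x, ...) {
  cat(sprintf("<fec_analysis> %d cycle(s), %d transition(s)\n",
              nrow(x$cycles), nrow(x$transitions)))
  print(dplyr::count(x$cycles, .data$label))
  invisible(x)
}

#' Force versus absolute contour length of every transition
#'
#' One row per rip: the average force before the transition against the
#' absolute (net unfolded) contour length of the preceding branch -- the
#' conventional scatter used to map intermediate-state stabilities.
#' Misfolded cycles are excluded by default, matching the convention of
#' quantifying intermediate states from traces without misfolding.
#'
#' @param analysis An `fec_analysis` from [analyze_cycles()].
#' @param include_misfolded Keep transitions from misfolded cycles.
#' @return A tibble: `molecule`, `cycle`, `sweep`, `direction`,
#'   `force_before_pN`, `lc_nm`, `label`.
#' @export
force_vs_lc_table <- function(analysis, include_misfolded = FALSE) {
  if (!inherits(analysis, "fec_analysis")) {
    stop_invalid("`analysis` must come from `analyze_cycles()`.")
  }
  tr <- analysis$transitions %>%
    left_join(select(analysis$cycles, "molecule", "cycle", "label"),
              by = c("molecule", "cycle"))
  if (!include_misfolded) {
    tr <- filter(tr, .data$label != "misfolded" | is.na(.data$label))
  }
  tr %>%
    mutate(lc_nm = .data$lc_before_nm) %>%
    select("molecule", "cycle", "sweep", "direction", "force_before_pN",
           "lc_nm", "label")
}
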