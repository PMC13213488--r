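# Delimited-text readers/writers for traces and assay tables, YAML run
# configuration, and the end-to-end pipeline driver.

trace_cols <- c("time_s", "extension_nm", "force_pN")

#' Read / write force-extension traces
#'
#' Traces are exchanged as tab-separated text with a header naming the units:
#' `time_s`, `extension_nm`, `force_pN`, plus optional `molecule`, `cycle`
#' and `sweep` columns for multi-cycle files.  Reading validates the header
#' and checks that time is strictly increasing within each sweep.
#'
#' @param path File path.
#' @param trace A data frame with at least the three trace columns.
#' @return `read_trace()` returns a tibble; `write_trace()` returns `path`
#'   invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trace_cols, names(out))
  if (length(missing)) {
    abort(sprintf("malformed trace header at line 1 of %s: missing column(s) %s",
                  path, paste(missing, collapse = ", ")),
          class = "ripfit_parse_error")
  }
  for (cl in trace_cols) {
    if (!is.numeric(out[[cl]])) {
      abort(sprintf("column `%s` of %s is not numeric", cl, path),
            class = "ripfit_parse_error")
    }
  }
  groups <- if (all(c("molecule", "cycle", "sweep") %in% names(out))) {
    split(out$time_s, interaction(out$molecule, out$cycle, out$sweep, drop = TRUE))
  } else list(out$time_s)
  for (g in groups) {
    if (length(g) > 1 && any(diff(g) <= 0)) {
      abort("time stamps are not strictly increasing within a sweep",
            class = "ripfit_parse_error")
    }
  }
  out
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  missing <- setdiff(trace_cols, names(trace))
  if (length(missing)) {
    stop_invalid(sprintf("trace is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  readr::write_tsv(trace, path, progress = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Bundles everything one pipeline run needs: the conditions to simulate,
#' experiment size, the seed, per-condition simulator overrides, and the
#' detection/classification thresholds (each documented at its function).
#' The object round-trips losslessly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param conditions Character vector of condition labels.
#' @param n_molecules,n_cycles Experiment size per condition.
#' @param seed Integer seed.
#' @param overrides Named list (per condition) of [sim_config()] argument
#'   overrides, e.g. `list(no_smap = list(misfold_prob = 0))`.
#' @param min_size,full_frac,misfold_force,bin_width Analysis thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions = c("no_smap", "atux", "dbk"),
                       n_molecules = 5, n_cycles = 5, seed = 1,
                       overrides = list(),
                       min_size = 10, full_frac = 0.9, misfold_force = 20,
                       bin_width = 5) {
  if (length(conditions) == 0) stop_invalid("`conditions` must not be empty.")
  bad <- setdiff(conditions, c("no_smap", "atux", "dbk"))
  if (length(bad)) stop_invalid(sprintf("unknown condition label '%s'", bad[1]))
  structure(list(conditions = conditions, n_molecules = n_molecules,
                 n_cycles = n_cycles, seed = seed, overrides = overrides,
                 min_size = min_size, full_frac = full_frac,
                 misfold_force = misfold_force, bin_width = bin_width),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the YAML serialization.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full simulate-detect-fit-classify pipeline
#'
#' For each condition: build the simulator configuration
#' ([sim_config()] + [apply_condition()] + overrides), simulate the
#' experiment, analyse every cycle ([analyze_cycles()]), and summarise the
#' contour-length-change distribution ([delta_lc_distribution()]).  All
#' randomness flows from the single seed, so a fixed configuration gives a
#' byte-identical report.
#'
#' @param config A [run_config()].
#' @return A list of class `fec_report`: `summaries` (one row per condition:
#'   peak location, zero-peak mass, per-class fractions, mean final
#'   unfolding force), `distributions` (named list of
#'   [delta_lc_distribution()] objects), `cycles`, `transitions`,
#'   `force_lc`, and `manifest` (every threshold with its value, the seed
#'   and a configuration hash).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_invalid("`config` must be a `run_config`.")
  summaries <- list(); dists <- list(); cyc <- list(); trs <- list(); flc <- list()
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[i]
    args <- config$overrides[[cond]] %||% list()
    sim_cfg <- apply_condition(do.call(sim_config, args), cond)
    sim <- simulate_experiment(sim_cfg, n_molecules = config$n_molecules,
                               n_cycles = config$n_cycles,
                               seed = config$seed + i - 1)
    an <- analyze_cycles(sim, constants = sim_cfg$constants,
                         min_size = config$min_size,
                         full_frac = config$full_frac,
                         misfold_force = config$misfold_force)
    dist <- delta_lc_distribution(an$cycles, bin_width = config$bin_width)
    truth_frac <- mean(sim$cycles$label == "misfolded")
    final_f <- an$transitions %>%
      filter(.data$sweep == "stretch", .data$direction == "unfold") %>%
      group_by(.data$molecule, .data$cycle) %>%
      summarise(f = dplyr::last(.data$force_before_pN), .groups = "drop")
    frac <- function(lbl) {
      r <- dist$fraction_by_class
      if (lbl %in% r$label) r$fraction[r$label == lbl] else 0
    }
    summaries[[i]] <- tibble(
      condition = cond,
      n_cycles = nrow(an$cycles),
      peak_dlc_nm = dist$peak_location_nm,
      peak_sd_nm = dist$peak_sd_nm,
      zero_peak_mass = dist$zero_peak_mass,
      frac_full = frac("full"),
      frac_misfolded = frac("misfolded"),
      frac_locked = frac("locked"),
      truth_frac_misfolded = truth_frac,
      mean_final_unfold_force_pN = mean(final_f$f)
    )
    dists[[cond]] <- dist
    cyc[[i]] <- mutate(an$cycles, condition = cond)
    trs[[i]] <- mutate(an$transitions, condition = cond)
    flc[[i]] <- mutate(force_vs_lc_table(an), condition = cond)
  }
  manifest <- tibble(
    parameter = c("seed", "n_molecules", "n_cycles", "min_size_nm",
                  "full_frac", "misfold_force_pN", "bin_width_nm",
                  "config_hash"),
    value = c(config$seed, config$n_molecules, config$n_cycles,
              config$min_size, config$full_frac, config$misfold_force,
              config$bin_width, rlang::hash(config))
  )
  structure(list(summaries = bind_rows(summaries),
                 distributions = dists,
                 cycles = bind_rows(cyc),
                 transitions = bind_rows(trs),
                 force_lc = bind_rows(flc),
                 manifest = manifest),
            class = "fec_report")
}

#' @export
print.fec_report <- function(x, ...) {
  cat("<fec_report>\n")
  print(x$summaries)
  invisible(x)
}
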