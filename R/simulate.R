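# Synthetic-data generator: kinetic Monte-Carlo simulation of constant-velocity
# stretch-relax cycles on a tandem-repeat protein tethered via DNA handles.
#
# The trap separation ramps linearly; at each kinetics step the force follows
# from a quasi-static balance between the trap and the current tether (the
# 78 kHz -> 100 Hz averaging of real acquisitions justifies ignoring sub-ms
# bead dynamics).  Cooperative blocks of repeats flip folded <-> unfolded with
# Bell rates k(F) = k0 exp(+/- F dx / kBT); flip times are sampled exactly for
# piecewise-constant rates via the cumulative-hazard inversion.

#' Simulation configuration
#'
#' Parameters of the pulling simulator.  Defaults emulate the experimental
#' conditions of the assay the package targets: a 589-residue, 15-repeat HEAT
#' protein pulled at 100 nm/s through two 600 bp DNA handles, acquired at high
#' bandwidth and averaged to 100 Hz.
#'
#' @param n_repeats Number of tandem repeats available as cooperative
#'   unfolding units.
#' @param residues_total Number of protein residues (sets the unfolded chain
#'   contour length through [wlc_constants()]).
#' @param pulling_speed Trap speed in nm/s.
#' @param trap_stiffness Combined effective trap stiffness in pN/nm.
#' @param output_rate Output sampling rate in Hz after block averaging.
#' @param kinetics_timestep Kinetic Monte-Carlo step in s.
#' @param unfold_rate0 Zero-force unfolding rate per cooperative block (1/s).
#' @param unfold_distance Distance to the unfolding barrier in nm.
#' @param refold_rate0 Zero-force refolding rate per unfolded block (1/s).
#' @param refold_distance Distance to the refolding barrier in nm.
#' @param refold_max_force Refolding is only permitted below this force (pN),
#'   reproducing the stretch-relax hysteresis of non-equilibrium pulling.
#' @param force_noise_sd Gaussian force noise added at the output stage (pN).
#' @param condition One of `"no_smap"`, `"atux"`, `"dbk"`; condition-specific
#'   behaviour is switched on by [apply_condition()].
#' @param misfold_prob Target fraction of stretching traces in which a
#'   contiguous block of repeats misfolds and becomes non-unfoldable.
#'   Misfolding never occurs on a molecule's first pull, so
#'   [simulate_experiment()] scales the per-cycle probability applied from
#'   the second pull onward by `n_cycles / (n_cycles - 1)` to keep the
#'   overall trace fraction at this value.
#' @param misfold_span Integer range (length 2) of repeats a misfolded block
#'   sequesters.  The lower default of 2 keeps the sequestered contour change
#'   large enough that a misfolded cycle always falls below the 90%
#'   full-unfolding classification threshold.
#' @param lock_after_unfold If `TRUE`, molecules may lock in the unfolded
#'   state after their first complete unfolding (refolding switched off).
#' @param lock_prob Per-molecule probability of locking.
#' @param stabilization_factor Multiplier (< 1) applied to `unfold_rate0`
#'   under the stabilising-ligand condition, raising unfolding forces.
#' @param boundary_prob Probability that any inter-repeat junction is a block
#'   boundary when a cycle's cooperative partition is drawn (heterogeneity of
#'   intermediates between consecutive pulls).
#' @param stability_sd Per-block stability heterogeneity: each block's
#'   zero-force unfolding rate is scaled by `10^rnorm(1, 0, stability_sd)`,
#'   redrawn every cycle, spreading rip forces over several pN the way
#'   domains of different stabilities do.
#' @param force_min Tension at the start of the stretch sweep (pN).
#' @param force_max Force reached at the end of the stretch when the protein
#'   is fully unfolded (pN); sets the trap travel.
#' @param constants A [wlc_constants()] object; its `residues`/`n_repeats`
#'   are kept in sync with the corresponding arguments.
#' @param seed Optional default seed used by [simulate_experiment()] when no
#'   seed argument is given.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_repeats = 15,
                       residues_total = 589,
                       pulling_speed = 100,
                       trap_stiffness = 0.3,
                       output_rate = 100,
                       kinetics_timestep = 1e-4,
                       unfold_rate0 = 4e-6,
                       unfold_distance = 8,
                       refold_rate0 = 100,
                       refold_distance = 8,
                       refold_max_force = 8,
                       force_noise_sd = 0.2,
                       condition = c("no_smap", "atux", "dbk"),
                       misfold_prob = 0,
                       misfold_span = c(2L, 8L),
                       lock_after_unfold = FALSE,
                       lock_prob = 0.33,
                       stabilization_factor = 0.1,
                       boundary_prob = 0.03,
                       stability_sd = 0.3,
                       force_min = 0.5,
                       force_max = 25,
                       constants = NULL,
                       seed = NULL) {
  condition <- match.arg(condition)
  check_number(n_repeats, "n_repeats", min = 1)
  check_number(pulling_speed, "pulling_speed", min = 0, allow_zero = FALSE)
  check_number(trap_stiffness, "trap_stiffness", min = 0, allow_zero = FALSE)
  check_number(output_rate, "output_rate", min = 0, allow_zero = FALSE)
  check_number(kinetics_timestep, "kinetics_timestep", min = 0, allow_zero = FALSE)
  check_number(unfold_rate0, "unfold_rate0", min = 0)
  check_number(unfold_distance, "unfold_distance", min = 0, allow_zero = FALSE)
  check_number(refold_rate0, "refold_rate0", min = 0)
  check_number(refold_distance, "refold_distance", min = 0, allow_zero = FALSE)
  check_number(misfold_prob, "misfold_prob", min = 0, max = 1)
  check_number(lock_prob, "lock_prob", min = 0, max = 1)
  check_number(stabilization_factor, "stabilization_factor", min = 0, allow_zero = FALSE)
  if (output_rate > 1 / kinetics_timestep) {
    stop_invalid("`output_rate` must not exceed 1 / `kinetics_timestep`.")
  }
  constants <- constants %||% wlc_constants(residues = residues_total,
                                            n_repeats = n_repeats)
  constants$residues <- residues_total
  constants$n_repeats <- n_repeats
  constants <- do.call(wlc_constants, constants[setdiff(names(constants),
                       c("handle_lc", "chain_total", "expected_dlc"))])
  structure(
    list(n_repeats = as.integer(n_repeats), residues_total = residues_total,
         pulling_speed = pulling_speed, trap_stiffness = trap_stiffness,
         output_rate = output_rate, kinetics_timestep = kinetics_timestep,
         unfold_rate0 = unfold_rate0, unfold_distance = unfold_distance,
         refold_rate0 = refold_rate0, refold_distance = refold_distance,
         refold_max_force = refold_max_force,
         force_noise_sd = force_noise_sd, condition = condition,
         misfold_prob = misfold_prob,
         misfold_span = as.integer(misfold_span),
         lock_after_unfold = lock_after_unfold, lock_prob = lock_prob,
         stabilization_factor = stabilization_factor,
         boundary_prob = boundary_prob, stability_sd = stability_sd,
         force_min = force_min, force_max = force_max,
         constants = constants, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: %s> %d repeats / %d residues, %g nm/s, trap %g pN/nm\n",
    x$condition, x$n_repeats, x$residues_total, x$pulling_speed,
    x$trap_stiffness))
  cat(sprintf("  Bell kinetics: k_u0 = %g /s (dx %g nm), k_r0 = %g /s (dx %g nm, F < %g pN)\n",
              x$unfold_rate0, x$unfold_distance, x$refold_rate0,
              x$refold_distance, x$refold_max_force))
  cat(sprintf("  misfold_prob = %g, lock = %s (p = %g), stabilization x%g\n",
              x$misfold_prob, x$lock_after_unfold, x$lock_prob,
              x$stabilization_factor))
  invisible(x)
}

#' Switch a configuration to one of the three experimental conditions
#'
#' * `no_smap`: misfolding enabled so that 22% of stretching traces misfold
#'   (the observed misfolded fraction of the condition); first pulls never
#'   misfold, later pulls compensate.
#' * `atux` (stabilising ligand): no misfolding; all unfolding rates scaled
#'   down by `stabilization_factor`, raising transition forces.
#' * `dbk` (folding-blocking ligand): after a molecule's first complete
#'   unfolding it locks in the unfolded state with probability `lock_prob`
#'   (refolding rates set to zero for all subsequent sweeps).
#'
#' @param config A [sim_config()].
#' @param condition Condition label; defaults to `config$condition`.
#' @return The modified configuration.
#' @export
apply_condition <- function(config, condition = config$condition) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` must be a `sim_config`.")
  if (!condition %in% c("no_smap", "atux", "dbk")) {
    stop_invalid(sprintf("unknown condition label '%s'", condition))
  }
  config$condition <- condition
  if (condition == "no_smap") {
    config$misfold_prob <- 0.22
    config$lock_after_unfold <- FALSE
  } else if (condition == "atux") {
    config$misfold_prob <- 0
    config$lock_after_unfold <- FALSE
    config$unfold_rate0 <- config$unfold_rate0 * config$stabilization_factor
  } else {
    config$misfold_prob <- 0
    config$lock_after_unfold <- TRUE
  }
  config
}

#' Draw a cooperative-block partition for one cycle
#'
#' Each of the `n_repeats - 1` inter-repeat junctions becomes a block boundary
#' independently with probability `boundary_prob`, producing 1--`n_repeats`
#' cooperative blocks whose contour-length changes sum exactly to the expected
#' full-unfolding value.  Resampled for every cycle, this reproduces the
#' heterogeneity in the number and size of intermediates between consecutive
#' pulls.  Uses the current RNG stream; seed with `set.seed()` or via
#' [simulate_experiment()].
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per block: `block`, `start_repeat`,
#'   `n_repeats`, `dlc_nm`.
#' @export
sample_partition <- function(config) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` must be a `sim_config`.")
  nr <- config$n_repeats
  per_repeat <- config$constants$expected_dlc / nr
  if (nr == 1L) {
    boundaries <- integer(0)
  } else {
    boundaries <- which(runif(nr - 1L) < config$boundary_prob)
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, nr)
  tibble(
    block = seq_along(starts),
    start_repeat = starts,
    n_repeats = ends - starts + 1L,
    dlc_nm = (ends - starts + 1L) * per_repeat
  )
}

# Draw a contiguous misfold-sequestered span of repeats; returns integer
# vector of repeat indices.
sample_misfold_span <- function(config) {
  lo <- min(config$misfold_span)
  hi <- min(max(config$misfold_span), config$n_repeats)
  size <- if (hi > lo) sample(lo:hi, 1L) else lo
  size <- min(size, config$n_repeats)
  start <- sample(config$n_repeats - size + 1L, 1L)
  seq(start, start + size - 1L)
}

# Partition respecting a sequestered span: the sequestered repeats form one
# block flagged non-unfoldable; remaining runs of repeats are partitioned as
# usual.
partition_with_misfold <- function(config, sequestered) {
  nr <- config$n_repeats
  per_repeat <- config$constants$expected_dlc / nr
  runs <- split(setdiff(seq_len(nr), sequestered),
                cumsum(c(1, diff(setdiff(seq_len(nr), sequestered))) != 1))
  blocks <- list(tibble(start_repeat = min(sequestered),
                        n_repeats = length(sequestered),
                        sequestered = TRUE))
  for (r in runs) {
    if (length(r) == 0) next
    nb <- length(r)
    bnd <- if (nb > 1) which(runif(nb - 1) < config$boundary_prob) else integer(0)
    starts <- c(1L, bnd + 1L)
    ends <- c(bnd, nb)
    blocks <- c(blocks, list(tibble(start_repeat = r[starts],
                                    n_repeats = ends - starts + 1L,
                                    sequestered = FALSE)))
  }
  out <- bind_rows(blocks) %>% arrange(.data$start_repeat)
  out$block <- seq_len(nrow(out))
  out$dlc_nm <- out$n_repeats * per_repeat
  out[, c("block", "start_repeat", "n_repeats", "dlc_nm", "sequestered")]
}

# Trap-separation end points: start at force_min with the protein folded,
# stop where the fully unfolded tether reaches force_max.
sweep_range <- function(config) {
  k <- config$trap_stiffness
  cst <- config$constants
  folded <- repeat_tether(0, cst)
  unfolded <- repeat_tether(cst$expected_dlc, cst)
  s0 <- tether_extension(config$force_min, folded) + config$force_min / k
  s1 <- tether_extension(config$force_max, unfolded) + config$force_max / k
  c(s0, s1)
}

# One constant-velocity sweep with kinetic Monte-Carlo block flips.
#
# s_t: trap separations at kinetics resolution; blocks: tibble from
# partition_* with logical columns; unfolded: logical start state; refolding
# allowed unless `locked`.  Returns full-resolution force series, final state
# and the event list.
run_sweep <- function(config, grid, s_t, blocks, unfolded, locked = FALSE) {
  dt <- config$kinetics_timestep
  k <- config$trap_stiffness
  kbt <- config$constants$kbt
  n <- length(s_t)
  force <- numeric(n)
  events <- list()
  sequestered <- blocks$sequestered %||% rep(FALSE, nrow(blocks))

  mult <- blocks$mult %||% rep(1, nrow(blocks))

  i <- 1L
  while (i <= n) {
    ell <- sum(blocks$dlc_nm[unfolded])
    s_of_f <- grid$a + ell * grid$b + grid$force / k
    f_rem <- approx(s_of_f, grid$force, xout = s_t[i:n], rule = 2)$y

    foldable <- which(!unfolded & !sequestered)
    refoldable <- if (locked) integer(0) else which(unfolded)
    ku <- if (length(foldable)) {
      sum(mult[foldable]) * config$unfold_rate0 *
        exp(f_rem * config$unfold_distance / kbt)
    } else 0
    kr <- if (length(refoldable)) {
      ifelse(f_rem < config$refold_max_force,
             config$refold_rate0 * exp(-f_rem * config$refold_distance / kbt),
             0)
    } else 0
    total <- ku + length(refoldable) * kr
    if (all(total == 0)) {
      force[i:n] <- f_rem
      break
    }
    hazard <- cumsum(total) * dt
    u <- runif(1)
    j <- findInterval(-log(u), hazard) + 1L
    if (j > length(f_rem)) {
      force[i:n] <- f_rem
      break
    }
    force[i:(i + j - 1L)] <- f_rem[seq_len(j)]
    f_ev <- f_rem[j]
    rate_u <- if (length(foldable)) sum(mult[foldable]) * config$unfold_rate0 *
      exp(f_ev * config$unfold_distance / kbt) else 0
    rate_r <- if (length(refoldable)) length(refoldable) *
      (if (f_ev < config$refold_max_force)
        config$refold_rate0 * exp(-f_ev * config$refold_distance / kbt) else 0) else 0
    unfold_event <- runif(1) < rate_u / (rate_u + rate_r)
    pick <- if (unfold_event) {
      w <- mult[foldable]
      foldable[sample.int(length(foldable), 1L, prob = w)]
    } else {
      refoldable[sample.int(length(refoldable), 1L)]
    }
    ell_new <- ell + if (unfold_event) blocks$dlc_nm[pick] else -blocks$dlc_nm[pick]
    # equilibrium extension jump at fixed separation: (F_before - F_after)/k
    s_new <- grid$a + ell_new * grid$b + grid$force / k
    f_after <- approx(s_new, grid$force, xout = s_t[i + j - 1L], rule = 2)$y
    unfolded[pick] <- unfold_event
    events[[length(events) + 1L]] <- tibble(
      step = i + j - 1L,
      time_s = (i + j - 2L) * dt,
      direction = if (unfold_event) "unfold" else "refold",
      force_pN = f_ev,
      delta_lc_nm = if (unfold_event) blocks$dlc_nm[pick] else -blocks$dlc_nm[pick],
      ext_jump_nm = (f_ev - f_after) / k,
      block = blocks$block[pick],
      block_repeats = blocks$n_repeats[pick]
    )
    i <- i + j
  }
  list(force = force,
       events = if (length(events)) bind_rows(events) else empty_events(),
       unfolded = unfolded)
}

empty_events <- function() {
  tibble(step = integer(), time_s = numeric(), direction = character(),
         force_pN = numeric(), delta_lc_nm = numeric(), ext_jump_nm = numeric(),
         block = integer(), block_repeats = integer())
}

# Block-average a full-resolution sweep down to the output rate and add the
# output-stage force noise.  Extension is the tether end-to-end distance
# s - F/k; the measured force noise propagates into it with weight -1/k.
decimate_sweep <- function(config, s_t, force) {
  dt <- config$kinetics_timestep
  n_dec <- max(1L, round(1 / (config$output_rate * dt)))
  n_out <- floor(length(s_t) / n_dec)
  idx <- seq_len(n_out * n_dec)
  t_full <- (idx - 1L) * dt
  x_full <- s_t[idx] - force[idx] / config$trap_stiffness
  f_mean <- colMeans(matrix(force[idx], nrow = n_dec))
  x_mean <- colMeans(matrix(x_full, nrow = n_dec))
  t_mean <- colMeans(matrix(t_full, nrow = n_dec))
  noise <- rnorm(n_out, 0, config$force_noise_sd)
  tibble(
    time_s = t_mean,
    extension_nm = x_mean - noise / config$trap_stiffness,
    force_pN = f_mean + noise
  )
}

# Mean force over the `window` seconds preceding each event (same estimator
# the rip analysis applies to measured traces).
event_window_force <- function(events, force, dt, window = 0.05) {
  if (nrow(events) == 0) return(numeric(0))
  nw <- max(1L, round(window / dt))
  vapply(events$step, function(j) {
    lo <- max(1L, j - nw)
    if (j <= 1L) force[1L] else mean(force[lo:(j - 1L)])
  }, numeric(1))
}

#' Simulate one stretch-relax cycle
#'
#' Runs the kinetic Monte-Carlo engine for a single pull-relax cycle and
#' returns the two decimated traces together with the ground-truth record of
#' every block flip.  Identical `(config, seed)` pairs give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (set before any random draw).
#' @param cycle Cycle number within the molecule; misfolding is only possible
#'   for `cycle >= 2`.
#' @param locked If `TRUE` the molecule is locked unfolded: the sweep starts
#'   from the fully unfolded state and refolding is disabled.
#' @param may_lock If `TRUE` (folding-blocking condition, lock not yet
#'   decided for this molecule) and the stretch ends with complete unfolding,
#'   the molecule locks with probability `lock_prob` before the relax sweep,
#'   so an engaging cycle shows unfolding rips on stretch but no refolds.
#' @param sweeps Which sweeps to simulate (`"both"` or `"stretch"`; relax is
#'   skipped during kinetic calibration for speed).
#' @param grid Optional precomputed [tether_grid()] (internal fast path).
#' @return A list of class `fec_cycle` with elements `stretch` and `relax`
#'   (tibbles: `time_s`, `extension_nm`, `force_pN`), and `truth`, a list with
#'   `events` (one row per flip: time, pre-flip force, windowed pre-flip
#'   force, signed contour change, extension jump) and `cycle` (one-row
#'   summary: misfold flag and sequestered contour, lock flags, completeness,
#'   max force).
#' @export
simulate_cycle <- function(config, seed = NULL, cycle = 1L, locked = FALSE,
                           may_lock = FALSE, sweeps = c("both", "stretch"),
                           grid = NULL) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` must be a `sim_config`.")
  sweeps <- match.arg(sweeps)
  if (!is.null(seed)) set.seed(seed)
  dt <- config$kinetics_timestep
  grid <- grid %||% tether_grid(config$constants,
                                f_max = max(80, 3 * config$force_max))
  rng <- sweep_range(config)
  n_steps <- ceiling((rng[2] - rng[1]) / (config$pulling_speed * dt))
  s_up <- rng[1] + config$pulling_speed * dt * (seq_len(n_steps) - 1L)
  s_down <- rev(s_up)

  misfold <- FALSE
  sequestered_dlc <- 0
  if (!locked && cycle >= 2L && config$misfold_prob > 0 &&
      runif(1) < config$misfold_prob) {
    misfold <- TRUE
    span <- sample_misfold_span(config)
    blocks <- partition_with_misfold(config, span)
    sequestered_dlc <- sum(blocks$dlc_nm[blocks$sequestered])
  } else {
    blocks <- sample_partition(config)
    blocks$sequestered <- FALSE
  }
  # per-block stability multipliers, redrawn every cycle
  blocks$mult <- if (config$stability_sd > 0) {
    10^rnorm(nrow(blocks), 0, config$stability_sd)
  } else rep(1, nrow(blocks))

  start_unfolded <- rep(locked, nrow(blocks))
  up <- run_sweep(config, grid, s_up, blocks, start_unfolded, locked = locked)
  stretch <- decimate_sweep(config, s_up, up$force)
  up$events$force_window_pN <- event_window_force(up$events, up$force, dt)

  complete <- if (locked) FALSE else {
    !misfold && all(up$unfolded[!blocks$sequestered])
  }

  # per-molecule lock draw: once, immediately after the first complete
  # unfolding, so the engaging cycle's relax already shows no refolds
  lock_decided <- FALSE
  lock_engaged <- FALSE
  if (may_lock && complete) {
    lock_decided <- TRUE
    lock_engaged <- runif(1) < config$lock_prob
  }
  relax_locked <- locked || lock_engaged

  if (sweeps == "both") {
    down <- run_sweep(config, grid, s_down, blocks, up$unfolded,
                      locked = relax_locked)
    relax <- decimate_sweep(config, s_down, down$force)
    down$events$force_window_pN <- event_window_force(down$events, down$force, dt)
  } else {
    down <- list(events = empty_events(), unfolded = up$unfolded)
    down$events$force_window_pN <- numeric(0)
    relax <- NULL
  }

  events <- bind_rows(
    mutate(up$events, sweep = "stretch"),
    mutate(down$events, sweep = "relax")
  )
  truth_cycle <- tibble(
    cycle = as.integer(cycle),
    condition = config$condition,
    misfold = misfold,
    misfold_dlc_nm = sequestered_dlc,
    locked = locked,
    lock_decided = lock_decided,
    lock_engaged = lock_engaged,
    complete_unfold = complete,
    attainable_dlc_nm = if (locked) 0 else config$constants$expected_dlc - sequestered_dlc,
    n_blocks = nrow(blocks),
    max_force_pN = max(up$force),
    label = if (locked) "locked" else if (misfold) "misfolded" else "full"
  )
  structure(list(stretch = stretch, relax = relax,
                 truth = list(events = events, cycle = truth_cycle)),
            class = "fec_cycle")
}

#' Simulate a multi-molecule pulling experiment
#'
#' Loops [simulate_cycle()] over molecules and cycles under one seeded RNG
#' stream, handling the per-molecule state the conditions require: misfolding
#' is drawn per stretch (never on first pulls), and under the
#' folding-blocking condition each molecule may lock in the unfolded state
#' (probability `lock_prob`, drawn once, after its first complete unfolding).
#'
#' @param config A [sim_config()], typically after [apply_condition()].
#' @param n_molecules,n_cycles Number of molecules and of stretch-relax
#'   cycles per molecule.
#' @param seed Integer seed for the whole experiment (defaults to
#'   `config$seed`).
#' @param sweeps Passed to [simulate_cycle()].
#' @return A list of class `fec_experiment`: `traces` (long tibble with
#'   `molecule`, `cycle`, `sweep`, `time_s`, `extension_nm`, `force_pN`),
#'   `events` (all truth flips), `cycles` (per-cycle truth), and `config`.
#' @examples
#' cfg <- apply_condition(sim_config(), "no_smap")
#' exp <- simulate_experiment(cfg, n_molecules = 1, n_cycles = 2, seed = 7)
#' dplyr::count(exp$traces, cycle, sweep)
#' @export
simulate_experiment <- function(config, n_molecules = 1L, n_cycles = 1L,
                                seed = NULL, sweeps = c("both", "stretch")) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` must be a `sim_config`.")
  sweeps <- match.arg(sweeps)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  # first pulls never misfold: compensate the per-cycle probability so the
  # expected fraction of ALL stretching traces equals misfold_prob
  if (n_cycles > 1L && config$misfold_prob > 0) {
    config$misfold_prob <- min(1, config$misfold_prob * n_cycles / (n_cycles - 1L))
  }
  grid <- tether_grid(config$constants, f_max = max(80, 3 * config$force_max))
  traces <- list()
  events <- list()
  cycles <- list()
  for (m in seq_len(n_molecules)) {
    locked <- FALSE
    lock_decided <- FALSE
    for (cy in seq_len(n_cycles)) {
      may_lock <- config$lock_after_unfold && !locked && !lock_decided
      res <- simulate_cycle(config, seed = NULL, cycle = cy, locked = locked,
                            may_lock = may_lock, sweeps = sweeps, grid = grid)
      if (res$truth$cycle$lock_decided) {
        lock_decided <- TRUE
        locked <- res$truth$cycle$lock_engaged
      }
      tr <- bind_rows(
        mutate(res$stretch, sweep = "stretch"),
        if (!is.null(res$relax)) mutate(res$relax, sweep = "relax")
      )
      tr$molecule <- m
      tr$cycle <- as.integer(cy)
      traces[[length(traces) + 1L]] <- tr
      ev <- res$truth$events
      if (nrow(ev)) {
        ev$molecule <- m
        ev$cycle <- as.integer(cy)
      }
      events[[length(events) + 1L]] <- ev
      cyrow <- res$truth$cycle
      cyrow$molecule <- m
      cycles[[length(cycles) + 1L]] <- cyrow
    }
  }
  traces <- bind_rows(traces) %>%
    select("molecule", "cycle", "sweep", "time_s", "extension_nm", "force_pN")
  events <- bind_rows(events)
  cycles <- bind_rows(cycles) %>% select("molecule", dplyr::everything())
  structure(list(traces = traces, events = events, cycles = cycles,
                 config = config),
            class = "fec_experiment")
}

#' @export
print.fec_experiment <- function(x, ...) {
  cat(sprintf("<fec_experiment: %s> %d molecule(s), %d cycle trace(s), %d truth flips\n",
              x$config$condition, length(unique(x$traces$molecule)),
              nrow(x$cycles), nrow(x$events)))
  invisible(x)
}

#' Calibrate the zero-force unfolding rate to a target mean unfolding force
#'
#' Bisects `log10(unfold_rate0)` until the simulated mean force of the final
#' unfolding transition matches `target_mean_force`.  The objective is
#' measured exactly the way the rip analysis measures it on real traces:
#' [detect_transitions()] is run on each simulated stretch sweep and the
#' pre-rip windowed force of the last unfolding rip of at least `min_size`
#' nm is averaged over cycles, so the calibrated quantity is commensurate
#' with the analysis output.  Each evaluation reuses the same sub-seed
#' (common random numbers), which makes the objective a smooth monotone
#' function of the rate and the search reproducible.
#'
#' @param config A [sim_config()].
#' @param target_mean_force Target mean final-unfolding force in pN; must lie
#'   in (1, 50).
#' @param n_cycles Stretch cycles simulated per objective evaluation.
#' @param seed Integer seed for the calibration stream.
#' @param bracket Range of `log10(unfold_rate0)` searched.
#' @param tol Stop once the achieved mean is within `tol` pN of the target.
#' @param min_size Minimum detectable extension jump in nm.
#' @return A list of class `rate_calibration` with `unfold_rate0`,
#'   `achieved_mean_force`, `n_cycles`, `iterations` and the evaluation trace.
#' @export
calibrate_unfold_kinetics <- function(config, target_mean_force = 7.2,
                                      n_cycles = 100L, seed = 1L,
                                      bracket = c(-8, -1), tol = 0.1,
                                      min_size = 10) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` must be a `sim_config`.")
  if (target_mean_force <= 1 || target_mean_force >= 50) {
    stop_invalid("`target_mean_force` must lie in (1, 50) pN.")
  }
  cfg <- config
  cfg$misfold_prob <- 0
  cfg$lock_after_unfold <- FALSE

  mean_final_force <- function(log_k0) {
    cfg$unfold_rate0 <- 10^log_k0
    sim <- simulate_experiment(cfg, n_molecules = n_cycles, n_cycles = 1L,
                               seed = seed, sweeps = "stretch")
    finals <- vapply(split(sim$traces, sim$traces$molecule), function(tr) {
      det <- detect_transitions(tr, min_size = min_size)
      det <- det[det$direction == "unfold", , drop = FALSE]
      if (nrow(det) == 0) NA_real_ else det$force_before_pN[nrow(det)]
    }, numeric(1))
    mean(finals, na.rm = TRUE)
  }

  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- mean_final_force(lo)
  f_hi <- mean_final_force(hi)
  # mean force decreases with the rate: f_lo is the high-force end.  At the
  # extremes no rip may be detectable at all (unfolding beyond the sweep for
  # tiny rates, or at forces too low to resolve for huge ones); interpret
  # accordingly.
  if (is.na(f_lo)) f_lo <- Inf
  if (is.na(f_hi)) f_hi <- -Inf
  if (!(f_lo > target_mean_force && f_hi < target_mean_force)) {
    abort(sprintf(
      "calibration bracket [1e%g, 1e%g] /s does not bracket the %g pN target (achieves %.2f..%.2f pN)",
      bracket[1], bracket[2], target_mean_force, f_hi, f_lo),
      class = "ripfit_calibration_error")
  }
  trace <- tibble(log10_rate = c(lo, hi), mean_force_pN = c(f_lo, f_hi))
  achieved <- NA_real_
  it <- 0L
  while (it < 24L) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- mean_final_force(mid)
    trace <- bind_rows(trace, tibble(log10_rate = mid, mean_force_pN = f_mid))
    if (is.na(f_mid)) {   # no detectable rip: rate far too high
      hi <- mid
      next
    }
    if (abs(f_mid - target_mean_force) <= tol || (hi - lo) < 0.02) {
      achieved <- f_mid
      lo <- hi <- mid
      break
    }
    if (f_mid > target_mean_force) lo <- mid else hi <- mid
  }
  if (is.na(achieved)) {
    mid <- (lo + hi) / 2
    achieved <- mean_final_force(mid)
  }
  structure(list(unfold_rate0 = 10^mid,
                 achieved_mean_force = achieved,
                 target_mean_force = target_mean_force,
                 n_cycles = n_cycles, iterations = it, trace = trace),
            class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat(sprintf(
    "<rate_calibration> unfold_rate0 = %.3g /s; mean final-unfolding force %.2f pN (target %.2f, %d cycles, %d iterations)\n",
    x$unfold_rate0, x$achieved_mean_force, x$target_mean_force, x$n_cycles,
    x$iterations))
  invisible(x)
}
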