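# Shared fixtures.  Expensive simulations are cached per test run so several
# test files can reuse the same seeded experiment.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .sim_cache)) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# A noiseless elastic sweep generated straight from the tether model at fixed
# net contour length: extension on a uniform trap ramp, force from the
# quasi-static balance.  Used as the null case for rip detection and as
# branch-fit input.
elastic_sweep <- function(lc = 0, f_min = 0.5, f_max = 20, n = 300,
                          noise = 0, constants = wlc_constants(), k = 0.3) {
  f <- seq(f_min, f_max, length.out = n)
  u <- lc / constants$expected_dlc
  x <- constants$handle_lc *
    ripfit:::ewlc_zeta(f, constants$handle_lp, constants$handle_k, constants$kbt) +
    constants$chain_total * u *
      ripfit:::ewlc_zeta(f, constants$protein_lp, constants$protein_k, constants$kbt) +
    constants$folded_span * (1 - u)
  eps <- if (noise > 0) rnorm(n, 0, noise) else numeric(n)
  tibble::tibble(time_s = seq_len(n) / 100,
                 extension_nm = x - eps / k,
                 force_pN = f + eps)
}

# Elastic sweep with instantaneous extension jumps injected at given sample
# indices (force drops by k * jump across each, as on a load line).
sweep_with_jumps <- function(jumps, at, n = 300, k = 0.3, noise = 0) {
  tr <- elastic_sweep(0, n = n, noise = noise)
  for (j in seq_along(jumps)) {
    idx <- at[j]:n
    tr$extension_nm[idx] <- tr$extension_nm[idx] + jumps[j]
    tr$force_pN[idx] <- tr$force_pN[idx] - k * jumps[j] * 0.15
  }
  tr
}

no_smap_sim <- function() {
  cached("no_smap_60", function() {
    cfg <- apply_condition(sim_config(), "no_smap")
    simulate_experiment(cfg, n_molecules = 12, n_cycles = 5, seed = 421)
  })
}

no_smap_analysis <- function() {
  cached("no_smap_60_an", function() analyze_cycles(no_smap_sim()))
}

dbk_sim <- function() {
  cached("dbk_30", function() {
    cfg <- apply_condition(sim_config(), "dbk")
    simulate_experiment(cfg, n_molecules = 6, n_cycles = 5, seed = 422)
  })
}

dbk_analysis <- function() {
  cached("dbk_30_an", function() analyze_cycles(dbk_sim()))
}
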