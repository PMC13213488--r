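# Kinetic Monte-Carlo pulling simulator: partition sampling, determinism,
# truth bookkeeping, hysteresis, and the three condition behaviours.

test_that("partition sampling conserves the expected contour change", {
  cfg <- sim_config()
  set.seed(1)
  for (i in 1:20) {
    p <- sample_partition(cfg)
    expect_true(nrow(p) >= 1 && nrow(p) <= 15)
    expect_true(all(p$n_repeats >= 1))
    expect_equal(sum(p$dlc_nm), cfg$constants$expected_dlc, tolerance = 1e-9)
  }
  # degenerate single-repeat protein: one block of the full change
  cfg1 <- sim_config(n_repeats = 1, residues_total = 589)
  p1 <- sample_partition(cfg1)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$dlc_nm, cfg1$constants$expected_dlc)
})

test_that("partitions are heterogeneous across draws", {
  cfg <- sim_config()
  set.seed(2)
  counts <- replicate(1000, nrow(sample_partition(cfg)))
  expect_gte(length(unique(counts)), 2)
})

test_that("identical config and seed give bit-identical traces", {
  cfg <- sim_config()
  a <- simulate_cycle(cfg, seed = 99)
  b <- simulate_cycle(cfg, seed = 99)
  expect_identical(a$stretch, b$stretch)
  expect_identical(a$relax, b$relax)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("without unfolding kinetics the stretch shows no rips", {
  cfg <- sim_config(unfold_rate0 = 0)
  res <- simulate_cycle(cfg, seed = 3, sweeps = "stretch")
  expect_identical(nrow(res$truth$events), 0L)
  d <- diff(res$stretch$extension_nm)
  expect_true(all(abs(d) < 10))
})

test_that("truth contour bookkeeping balances for clean cycles", {
  sim <- no_smap_sim()
  clean <- sim$cycles[!sim$cycles$misfold & !sim$cycles$locked, ]
  for (i in seq_len(min(10, nrow(clean)))) {
    ev <- sim$events[sim$events$molecule == clean$molecule[i] &
                       sim$events$cycle == clean$cycle[i] &
                       sim$events$sweep == "stretch", ]
    expect_equal(sum(ev$delta_lc_nm), sim$config$constants$expected_dlc,
                 tolerance = 1e-9)
  }
})

test_that("stretch-relax cycles show hysteresis", {
  sim <- no_smap_sim()
  un <- sim$events$force_pN[sim$events$direction == "unfold"]
  re <- sim$events$force_pN[sim$events$direction == "refold"]
  expect_gt(length(re), 0)
  expect_gt(mean(un), mean(re))
})

test_that("nearly all repeats unfold below 30 pN in non-misfolded cycles", {
  sim <- no_smap_sim()
  cyc <- sim$cycles[!sim$cycles$misfold & !sim$cycles$locked, ]
  expect_gte(mean(cyc$complete_unfold), 0.95)
  expect_true(all(cyc$max_force_pN < 35))
})

test_that("apply_condition implements the three experimental conditions", {
  base <- sim_config()
  expect_error(apply_condition(base, "banana"), class = "ripfit_invalid_input")

  ns <- apply_condition(base, "no_smap")
  expect_equal(ns$misfold_prob, 0.22)
  at <- apply_condition(base, "atux")
  expect_equal(at$misfold_prob, 0)
  expect_equal(at$unfold_rate0, base$unfold_rate0 * base$stabilization_factor)
  db <- apply_condition(base, "dbk")
  expect_true(db$lock_after_unfold)
})

test_that("no misfolding under the stabilising ligand, none on first pulls", {
  cfg <- apply_condition(sim_config(), "atux")
  sim <- cached("atux_20", function()
    simulate_experiment(cfg, n_molecules = 4, n_cycles = 5, seed = 77))
  expect_true(all(!sim$cycles$misfold))

  ns <- no_smap_sim()
  first <- ns$cycles[ns$cycles$cycle == 1, ]
  expect_true(all(!first$misfold))
  later <- ns$cycles[ns$cycles$cycle > 1, ]
  expect_gt(sum(later$misfold), 0)
})

test_that("stabilising ligand raises unfolding forces", {
  ns <- no_smap_sim()
  at <- cached("atux_20", function()
    simulate_experiment(apply_condition(sim_config(), "atux"),
                        n_molecules = 4, n_cycles = 5, seed = 77))
  max_unfold <- function(s) {
    ev <- s$events[s$events$direction == "unfold", ]
    tapply(ev$force_pN, paste(ev$molecule, ev$cycle), max)
  }
  expect_gt(mean(max_unfold(at)), mean(max_unfold(ns)))
})

test_that("locked molecules show no transitions after the lock engages", {
  sim <- dbk_sim()
  locked <- sim$cycles[sim$cycles$locked, ]
  expect_gt(nrow(locked), 0)
  for (i in seq_len(nrow(locked))) {
    ev <- sim$events[sim$events$molecule == locked$molecule[i] &
                       sim$events$cycle == locked$cycle[i], ]
    expect_identical(nrow(ev), 0L)
  }
  # the cycle where the lock engaged still unfolds on stretch, but no refolds
  engaged <- sim$cycles[sim$cycles$lock_engaged, ]
  for (i in seq_len(nrow(engaged))) {
    ev <- sim$events[sim$events$molecule == engaged$molecule[i] &
                       sim$events$cycle == engaged$cycle[i], ]
    expect_gt(sum(ev$direction == "unfold"), 0)
    expect_identical(sum(ev$direction == "refold"), 0L)
  }
})

test_that("raising the unfolding rate lowers unfolding forces", {
  cfg <- sim_config()
  mean_force <- function(k0) {
    cfg$unfold_rate0 <- k0
    sim <- simulate_experiment(cfg, n_molecules = 12, n_cycles = 1,
                               seed = 55, sweeps = "stretch")
    mean(sim$events$force_pN[sim$events$direction == "unfold"])
  }
  expect_gt(mean_force(4e-6), mean_force(4e-5))
})

test_that("kinetic calibration reaches the target mean unfolding force", {
  cal <- cached("calibration_small", function()
    calibrate_unfold_kinetics(sim_config(), target_mean_force = 7.2,
                              n_cycles = 40, seed = 11, tol = 0.15))
  expect_s3_class(cal, "rate_calibration")
  expect_lt(abs(cal$achieved_mean_force - 7.2), 0.3)
  expect_error(
    calibrate_unfold_kinetics(sim_config(), target_mean_force = 60),
    class = "ripfit_invalid_input")
})

test_that("independent calibrations agree to the slope-limited precision", {
  # A 0.15 pN tolerance on the objective corresponds to a rate band of
  # exp(0.15 * dx / kBT) ~ 1.34, so two runs on different streams should
  # land within about half a log10 decade of each other.
  cal1 <- cached("calibration_small", function()
    calibrate_unfold_kinetics(sim_config(), 7.2, n_cycles = 40, seed = 11,
                              tol = 0.15))
  cal2 <- cached("calibration_small2", function()
    calibrate_unfold_kinetics(sim_config(), 7.2, n_cycles = 40, seed = 12,
                              tol = 0.15))
  expect_lt(abs(log10(cal1$unfold_rate0) - log10(cal2$unfold_rate0)), 0.5)
})
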