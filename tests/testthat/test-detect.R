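# Rip detection, pre-rip force quantification, and tether validation.

test_that("noiseless elastic sweeps produce no transitions", {
  for (lc in c(0, 100, 199.985)) {
    tr <- elastic_sweep(lc)
    expect_identical(nrow(detect_transitions(tr)), 0L)
  }
})

test_that("no false positives over 100 noiseless sweeps", {
  set.seed(31)
  lcs <- runif(100, 0, 199)
  n_fp <- sum(vapply(lcs, function(lc)
    nrow(detect_transitions(elastic_sweep(lc))), numeric(1)))
  expect_identical(n_fp, 0)
})

test_that("the minimum-size threshold separates 15 nm from 8 nm jumps", {
  tr <- sweep_with_jumps(jumps = c(15, 8), at = c(100, 200))
  det <- detect_transitions(tr, min_size = 10)
  expect_identical(nrow(det), 1L)
  expect_equal(det$extension_jump_nm, 15, tolerance = 1.5)
  expect_identical(det$direction, "unfold")
})

test_that("raising min_size never increases the transition count", {
  tr <- sweep_with_jumps(jumps = c(6, 15, 25), at = c(80, 160, 240),
                         noise = 0.2)
  counts <- vapply(c(5, 10, 20, 30),
                   function(ms) nrow(detect_transitions(tr, min_size = ms)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trace validation catches malformed input", {
  tr <- elastic_sweep(0)
  expect_error(detect_transitions(tr[1:20, ]), class = "ripfit_invalid_trace")
  bad <- tr; bad$time_s <- rev(bad$time_s)
  expect_error(detect_transitions(bad), class = "ripfit_invalid_trace")
  expect_error(detect_transitions(tr[, 1:2]), class = "ripfit_invalid_trace")
})

test_that("detection recalls large truth rips and measures their size", {
  sim <- no_smap_sim()
  traces <- sim$traces[sim$traces$sweep == "stretch", ]
  keys <- unique(traces[, c("molecule", "cycle")])
  n_truth <- 0; n_hit <- 0; size_err <- c()
  for (i in seq_len(nrow(keys))) {
    tr <- traces[traces$molecule == keys$molecule[i] &
                   traces$cycle == keys$cycle[i], ]
    det <- detect_transitions(tr)
    evc <- sim$events[sim$events$molecule == keys$molecule[i] &
                        sim$events$cycle == keys$cycle[i] &
                        sim$events$sweep == "stretch", ]
    ev <- evc[evc$direction == "unfold" & evc$ext_jump_nm >= 12, ]
    for (j in seq_len(nrow(ev))) {
      # a flip reversed by another flip within the averaging resolution
      # (3 output samples) leaves no resolvable signature in 100 Hz data
      reversed <- any(evc$direction == "refold" &
                        abs(evc$time_s - ev$time_s[j]) < 0.03)
      if (reversed) next
      n_truth <- n_truth + 1
      t_det <- tr$time_s[det$onset_index]
      hit <- which(abs(t_det - ev$time_s[j]) < 0.05)
      if (length(hit)) {
        n_hit <- n_hit + 1
        size_err <- c(size_err,
                      det$extension_jump_nm[hit[1]] - ev$ext_jump_nm[j])
      }
    }
  }
  expect_gt(n_truth, 10)
  expect_gte(n_hit / n_truth, 0.95)
  expect_lt(median(abs(size_err)), 2)
})

# a hand-built sweep: linear extension advance with an instantaneous rip and
# a matching force drop, force otherwise flat or gently rising
crafted_rip <- function(jump = 20, at = 150, n = 300, pre_force = 7,
                        ramp = NULL) {
  x <- 400 + 0.8 * seq_len(n) + ifelse(seq_len(n) >= at, jump, 0)
  f <- rep(pre_force, n)
  f[seq_len(n) >= at] <- pre_force - 2
  if (!is.null(ramp)) f[(at - length(ramp)):(at - 1)] <- ramp
  tibble::tibble(time_s = seq_len(n) / 100, extension_nm = x, force_pN = f)
}

test_that("pre-rip force is the windowed mean of the preceding branch", {
  tr <- crafted_rip(jump = 20, at = 150, pre_force = 7)
  det <- detect_transitions(tr)
  expect_identical(nrow(det), 1L)
  expect_equal(transition_force(tr, det), 7, tolerance = 1e-9)

  # linear ramp 6 -> 8 pN across the 5-sample window averages to its centre
  tr2 <- crafted_rip(jump = 20, at = 150, pre_force = 7,
                     ramp = seq(6, 8, length.out = 5))
  det2 <- detect_transitions(tr2)
  win <- tr2$force_pN[(det2$onset_index - 4):det2$onset_index]
  expect_equal(transition_force(tr2, det2), mean(win), tolerance = 1e-9)
  expect_equal(mean(win), 7, tolerance = 0.5)
})

test_that("a short preceding branch shrinks the window with a warning", {
  tr <- crafted_rip(jump = 20, at = 4)
  det <- detect_transitions(tr)
  expect_warning(transition_force(tr, det), class = "ripfit_window_shrunk")
})

test_that("measured rip forces track the truth on simulated cycles", {
  sim <- no_smap_sim()
  traces <- sim$traces[sim$traces$sweep == "stretch", ]
  keys <- unique(traces[, c("molecule", "cycle")])[1:12, ]
  diffs <- c()
  for (i in seq_len(nrow(keys))) {
    tr <- traces[traces$molecule == keys$molecule[i] &
                   traces$cycle == keys$cycle[i], ]
    det <- detect_transitions(tr)
    ev <- sim$events[sim$events$molecule == keys$molecule[i] &
                       sim$events$cycle == keys$cycle[i] &
                       sim$events$sweep == "stretch" &
                       sim$events$ext_jump_nm >= 12, ]
    for (j in seq_len(nrow(det))) {
      t_det <- tr$time_s[det$onset_index[j]]
      hit <- which(abs(ev$time_s - t_det) < 0.05)
      if (length(hit)) {
        diffs <- c(diffs, det$force_before_pN[j] - ev$force_window_pN[hit[1]])
      }
    }
  }
  expect_gt(length(diffs), 5)
  # noise sigma 0.2 pN over a 5-sample window, plus sub-sample onset jitter
  expect_lt(median(abs(diffs)), 0.5)
})

test_that("tether validation flags doubling and rupture", {
  tr <- elastic_sweep(0, n = 300)
  det <- detect_transitions(tr)
  expect_identical(validate_tether(tr, det, 200, total_dlc = 200), "valid")
  expect_identical(validate_tether(tr, det, 200, total_dlc = 400),
                   "multi_tether")

  # rupture: force collapses to zero mid-sweep and stays there
  rup <- elastic_sweep(0, f_min = 0.5, f_max = 20, n = 300)
  rup$force_pN[150:300] <- abs(rnorm(151, 0, 0.05))
  rup$extension_nm[150:300] <- rup$extension_nm[150] + seq(0, 150, length.out = 151)
  expect_identical(validate_tether(rup, det, 200, total_dlc = 200), "broken")
})
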