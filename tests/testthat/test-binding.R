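# Ensemble assays: nanoDSF Tm extraction and one-site FP binding fits.

test_that("polarization follows the intensity formula and its bounds", {
  expect_equal(polarization(100, 100), 0)
  expect_equal(polarization(100, 0), 1)
  expect_equal(polarization(150, 50), 0.5)
  expect_equal(polarization(150, 50, millipolarization = TRUE), 500)

  set.seed(5)
  ip <- runif(500, 0, 1e4); iq <- runif(500, 0, 1e4)
  p <- polarization(ip, iq)
  expect_true(all(p >= -1 & p <= 1))

  expect_error(polarization(-1, 5), class = "ripfit_invalid_input")
  expect_error(polarization(0, 0), class = "ripfit_undefined_polarization")
})

test_that("ratio derivative is flat for constant and linear ratios", {
  temp <- seq(20, 90, by = 0.5)
  flat <- tibble::tibble(temperature_C = temp, int330 = 5000,
                         int350 = 5000 * 1.1)
  d <- melt_ratio_derivative(flat)
  expect_true(all(abs(d$dfir) < 1e-12))

  m <- 0.004
  lin <- tibble::tibble(temperature_C = temp, int330 = 5000,
                        int350 = 5000 * (0.8 + m * temp))
  dl <- melt_ratio_derivative(lin)
  interior <- 5:(nrow(dl) - 4)
  expect_equal(dl$dfir[interior], rep(m, length(interior)), tolerance = 1e-8)

  bad <- flat; bad$int330[10] <- 0
  expect_error(melt_ratio_derivative(bad), class = "ripfit_invalid_curve")
  expect_error(melt_ratio_derivative(flat, smooth_window = 8),
               class = "ripfit_invalid_input")
  expect_error(melt_ratio_derivative(flat[1:10, ]),
               class = "ripfit_invalid_input")
})

test_that("sigmoid derivative peaks at the midpoint like finite differences", {
  curve <- generate_melt(tm = 55, width = 2, noise_sd = 0)
  d <- melt_ratio_derivative(curve)
  i <- which.max(abs(d$dfir))
  expect_equal(d$temperature_C[i], 55, tolerance = 0.1)

  # dense finite-difference oracle on the raw (unsmoothed) ratio
  ratio <- curve$int350 / curve$int330
  fd <- diff(ratio) / diff(curve$temperature_C)
  i_fd <- which.max(abs(fd))
  expect_equal(curve$temperature_C[i_fd], d$temperature_C[i], tolerance = 0.2)
})

test_that("Tm extraction recovers generated midpoints to 0.1 degC", {
  for (tm in c(52.7, 53.5)) {
    curve <- generate_melt(tm = tm, width = 2, noise_sd = 0, t_step = 0.1)
    got <- extract_tm(melt_ratio_derivative(curve))
    expect_equal(as.numeric(got), tm, tolerance = 0.1)
  }
  # convenience wrapper agrees
  ft <- fit_tm(generate_melt(tm = 52.7, noise_sd = 0))
  expect_equal(ft$tm_C, 52.7, tolerance = 0.1)
})

test_that("a transition-free melt raises a no-transition error", {
  curve <- generate_melt(tm = 55, amplitude = 0, noise_sd = 0)
  expect_error(extract_tm(melt_ratio_derivative(curve)),
               class = "ripfit_no_transition")
})

test_that("Tm error scales down with the ratio noise", {
  # locating a ~2 degC-wide derivative peak with a 7-point window leaves a
  # jitter proportional to the ratio noise: exact to the grid at 1e-4,
  # within a degree at 1e-3
  err_at <- function(noise) {
    vapply(1:20, function(s) {
      curve <- generate_melt(tm = 52.7, noise_sd = noise, seed = 3000 + s)
      abs(fit_tm(curve)$tm_C - 52.7)
    }, numeric(1))
  }
  e_small <- err_at(1e-4)
  e_large <- err_at(1e-3)
  expect_true(all(e_small <= 0.5))
  expect_true(all(e_large <= 1.5))
  expect_lt(median(e_small), median(e_large))
})

test_that("the forward FP model obeys the one-site isotherm exactly", {
  tt <- generate_fp(kd = 4.7, pmax = 100, noise_sd = 0)
  expect_equal(tt$p_mP, 100 * tt$conc_uM / (4.7 + tt$conc_uM))
  expect_equal(tt$p_mP[tt$conc_uM == 0], 0)
  half <- generate_fp(kd = 4.7, pmax = 100, concentrations = c(0, 1, 3, 4.7, 10, 40, 80),
                      noise_sd = 0)
  expect_equal(half$p_mP[half$conc_uM == 4.7], 50)
})

test_that("the one-site fit recovers Kd from noiseless data", {
  tt <- generate_fp(kd = 4.7, pmax = 100, noise_sd = 0)
  fit <- fit_one_site(tt)
  expect_equal(fit$kd_uM, 4.7, tolerance = 0.01)
  expect_equal(fit$pmax, 100, tolerance = 0.1)
  td <- tidy(fit)
  expect_identical(td$term, c("pmax", "kd"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$kd_uM, fit$kd_uM)
})

test_that("the fitted isotherm is increasing and saturates at Pmax", {
  tt <- generate_fp(kd = 4.7, pmax = 100, noise_sd = 2, n_replicates = 3,
                    seed = 17)
  fit <- fit_one_site(tt)
  cgrid <- seq(0.01, 500, length.out = 100)
  pc <- fit$pmax * cgrid / (fit$kd_uM + cgrid)
  expect_true(all(diff(pc) > 0))
  expect_lt(abs(pc[100] - fit$pmax) / fit$pmax, 0.02)
})

test_that("Kd is recovered within 25% under realistic noise", {
  kds <- vapply(1:10, function(s) {
    tt <- generate_fp(kd = 4.7, pmax = 100, noise_sd = 2, n_replicates = 3,
                      seed = 5000 + s)
    fit_one_site(tt)$kd_uM
  }, numeric(1))
  expect_true(all(abs(kds - 4.7) / 4.7 < 0.25))
})

test_that("inadmissible titrations are rejected", {
  expect_error(fit_one_site(tibble::tibble(conc_uM = c(0, 1, 2),
                                           p_mP = c(0, 10, 20))),
               class = "ripfit_invalid_input")
  expect_error(fit_one_site(tibble::tibble(conc_uM = c(1, 2, 3, 4, 5, 6),
                                           p_mP = 1:6)),
               class = "ripfit_invalid_input")
})
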