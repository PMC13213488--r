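# Branch-wise WLC fitting and contour-length-change assembly.

cst <- wlc_constants()

test_that("noiseless branches round-trip their contour length", {
  tr <- elastic_sweep(cst$expected_dlc, f_min = 2, f_max = 20, n = 200)
  ft <- fit_branch(tr, cst)
  expect_equal(ft$fitted_lc_nm, cst$expected_dlc, tolerance = 0.1,
               ignore_attr = TRUE)

  folded <- elastic_sweep(0, f_min = 2, f_max = 20, n = 200)
  ft0 <- fit_branch(folded, cst)
  expect_lt(abs(ft0$fitted_lc_nm), 2)
})

test_that("noisy branches recover Lc and agree with a grid-search oracle", {
  set.seed(101)
  tr <- elastic_sweep(100, f_min = 2, f_max = 20, n = 200, noise = 0.2)
  ft <- fit_branch(tr, cst, robust = FALSE)
  expect_equal(ft$fitted_lc_nm, 100, tolerance = 2, ignore_attr = TRUE)

  # independent oracle: dense grid over Lc, model force via the bisection
  # inverse (tether_force), not the interpolation path used by fit_branch
  ssr_oracle <- function(lc) {
    tm <- tether_model(
      c(list(wlc_params(cst$handle_lp, cst$handle_lc, cst$handle_k, cst$kbt)),
        if (lc > 0) list(wlc_params(cst$protein_lp,
                                    cst$chain_total * lc / cst$expected_dlc,
                                    cst$protein_k, cst$kbt))),
      rigid_offset = cst$folded_span * (1 - lc / cst$expected_dlc))
    fhat <- tether_force(tr$extension_nm, tm)
    sum((tr$force_pN - fhat)^2)
  }
  grid <- seq(95, 105, by = 0.25)
  lc_oracle <- grid[which.min(vapply(grid, ssr_oracle, numeric(1)))]
  expect_equal(ft$fitted_lc_nm, lc_oracle, tolerance = 0.5,
               ignore_attr = TRUE)
})

test_that("parameter recovery stays within 2 nm median error at default noise", {
  set.seed(102)
  errs <- c()
  for (lc in c(50, 100, 150, 199.985)) {
    for (r in 1:50) {
      tr <- elastic_sweep(lc, f_min = 2, f_max = 22, n = 150, noise = 0.2)
      ft <- fit_branch(tr, cst)
      errs <- c(errs, abs(ft$fitted_lc_nm - lc))
    }
  }
  expect_identical(length(errs), 200L)
  expect_lt(median(errs), 2)
})

test_that("clamped constants are echoed bitwise", {
  tr <- elastic_sweep(150, f_min = 2, f_max = 20, n = 100)
  ft <- fit_branch(tr, cst)
  expect_identical(ft$handle_lp, cst$handle_lp)
  expect_identical(ft$handle_lc, cst$handle_lc)
  expect_identical(ft$handle_k, cst$handle_k)
  expect_identical(ft$protein_lp, cst$protein_lp)
  expect_identical(ft$protein_k, cst$protein_k)
})

test_that("too-short or too-flat segments are skipped with a warning", {
  tr <- elastic_sweep(0, n = 200)
  expect_warning(out <- fit_branch(tr[1:5, ], cst),
                 class = "ripfit_short_branch")
  expect_null(out)
  flat <- tr[1:50, ]; flat$force_pN <- flat$force_pN * 0 + 5
  expect_warning(out2 <- fit_branch(flat, cst, min_span = 1),
                 class = "ripfit_short_branch")
  expect_null(out2)
})

test_that("cycle contour changes are differences of flanking branch fits", {
  trans <- tibble::tibble(direction = c("unfold", "unfold"),
                          onset_index = c(100L, 200L),
                          end_index = c(101L, 201L),
                          extension_jump_nm = c(20, 30),
                          force_before_pN = c(6, 7),
                          preceding_branch = 1:2, following_branch = 2:3)
  fits <- tibble::tibble(branch = 1:3, fitted_lc_nm = c(0, 80, 200))
  res <- cycle_delta_lc(trans, fits)
  expect_equal(res$transitions$delta_lc_nm, c(80, 120))
  expect_equal(res$total_dlc_nm, 200)
  expect_equal(sum(res$transitions$delta_lc_nm), res$total_dlc_nm,
               tolerance = 1e-6)
  expect_false(res$partial)

  # a two-branch cycle 0 -> 200
  res2 <- cycle_delta_lc(trans[1, ],
                         tibble::tibble(branch = 1:2, fitted_lc_nm = c(0, 200)))
  expect_equal(res2$total_dlc_nm, 200)

  # missing fit flags the result partial
  fits$fitted_lc_nm[2] <- NA_real_
  expect_warning(res3 <- cycle_delta_lc(trans, fits),
                 class = "ripfit_partial_cycle")
  expect_true(res3$partial)
})

test_that("detected rips on single-block cycles carry the full contour change", {
  an <- no_smap_analysis()
  sim <- no_smap_sim()
  one_block <- sim$cycles[sim$cycles$n_blocks == 1 & !sim$cycles$misfold, ]
  tr <- an$transitions[an$transitions$sweep == "stretch" &
                         an$transitions$direction == "unfold", ]
  got <- merge(tr, one_block[, c("molecule", "cycle")])
  expect_gt(nrow(got), 3)
  expect_lt(median(abs(got$delta_lc_nm - sim$config$constants$expected_dlc)), 4)
})

test_that("force-vs-Lc table excludes misfolded cycles by default", {
  an <- no_smap_analysis()
  tab <- force_vs_lc_table(an)
  expect_true(all(tab$label != "misfolded", na.rm = TRUE))
  expect_identical(nrow(tab),
                   nrow(merge(an$transitions,
                              an$cycles[an$cycles$label != "misfolded",
                                        c("molecule", "cycle")])))
  tab_all <- force_vs_lc_table(an, include_misfolded = TRUE)
  expect_gte(nrow(tab_all), nrow(tab))
  expect_true(all(c("force_before_pN", "lc_nm", "direction") %in% names(tab)))
})

test_that("an all-misfolded table is empty", {
  an <- no_smap_analysis()
  fake <- an
  fake$cycles$label <- "misfolded"
  expect_identical(nrow(force_vs_lc_table(fake)), 0L)
})
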