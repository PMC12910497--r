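test_that("baseline correction flattens a peak riding on a linear ramp", {
  tg <- gen_thermogram(tm = -18, dh = 5, fwhm = 2, eta = 0,
                       baseline_intercept = 0.2, baseline_slope = 0.01,
                       noise_sd = 0)
  bc <- baseline_correct(tg)
  flank <- tg$T_C < -30 | tg$T_C > -9
  height <- max(bc$cp_kcal_mol_C)
  expect_lt(mean(abs(bc$cp_kcal_mol_C[flank])), 0.01 * height)
})

test_that("baseline correction is idempotent on clean zero-baseline data", {
  tg <- gen_thermogram(tm = -20, dh = 6, fwhm = 2, eta = 0,
                       baseline_intercept = 0, baseline_slope = 0,
                       noise_sd = 0)
  bc <- baseline_correct(tg)
  expect_equal(bc$cp_kcal_mol_C, tg$cp_kcal_mol_C, tolerance = 1e-10)
})

test_that("zero signal stays zero and yields no transition", {
  tg <- tibble::tibble(T_C = seq(-40, -5, 0.05), cp_kcal_mol_C = 0)
  bc <- baseline_correct(tg)
  expect_equal(bc$cp_kcal_mol_C, rep(0, nrow(tg)))
  expect_error(analyze_transition(bc), class = "memphys_no_transition")
})

test_that("transition parameters are recovered from a clean endotherm", {
  tg <- gen_thermogram(tm = -16.68, dh = 8.34, fwhm = 1.5, eta = 0,
                       noise_sd = 0)
  tr <- analyze_transition(baseline_correct(tg))
  expect_equal(tr$Tm_C, -16.68, tolerance = 0.02 / 16.68)
  expect_lt(abs(tr$Tm_C - -16.68), 0.02)
  expect_equal(tr$dH_kcal_mol, 8.34, tolerance = 0.01)
  expect_equal(tr$fwhm_C, 1.5, tolerance = 0.02)
})

test_that("the dominant component of a two-peak mixture sets Tm", {
  grid <- seq(-40, -5, 0.05)
  mix <- 10 * memphys:::pseudo_voigt(grid, -20, 2, eta = 0) +
    1 * memphys:::pseudo_voigt(grid, -12, 2, eta = 0)
  tg <- tibble::tibble(T_C = grid, cp_kcal_mol_C = mix)
  tr <- analyze_transition(baseline_correct(tg))
  expect_equal(tr$Tm_C, -20, tolerance = 0.05)
})

test_that("a peak at the window edge is rejected", {
  tg <- gen_thermogram(tm = -39, dh = 5, fwhm = 1.5, noise_sd = 0)
  expect_error(baseline_correct(tg), class = "memphys_bad_window")
})

test_that("enthalpy is invariant under baseline offsets; scaling behaves linearly", {
  tg <- gen_thermogram(tm = -18, dh = 6, fwhm = 2, noise_sd = 0,
                       baseline_intercept = 0, baseline_slope = 0)
  tr0 <- analyze_transition(baseline_correct(tg))
  shifted <- tg
  shifted$cp_kcal_mol_C <- shifted$cp_kcal_mol_C + 0.8 - 0.02 * shifted$T_C
  tr1 <- analyze_transition(baseline_correct(shifted))
  expect_equal(tr1$dH_kcal_mol, tr0$dH_kcal_mol, tolerance = 5e-3)
  expect_equal(tr1$Tm_C, tr0$Tm_C, tolerance = 1e-3)
  scaled <- tg
  scaled$cp_kcal_mol_C <- 2.5 * scaled$cp_kcal_mol_C
  tr2 <- analyze_transition(baseline_correct(scaled))
  expect_equal(tr2$Tm_C, tr0$Tm_C, tolerance = 1e-6)
  expect_equal(tr2$dH_kcal_mol, 2.5 * tr0$dH_kcal_mol, tolerance = 1e-6)
})

test_that("parameters are recovered across 200 randomized noisy thermograms", {
  set.seed(2024)
  errs <- matrix(NA_real_, 200, 2)
  for (i in 1:200) {
    repeat {
      tm <- runif(1, -25, -10)
      fw <- runif(1, 0.8, 6)
      # the apex must sit between the baseline flanks and the peak inside
      # the scan window (analysis preconditions)
      if (tm + 2.2 * fw < -6 && tm - 2.2 * fw > -39 && tm < -11) break
    }
    dh <- runif(1, 0.4, 10)
    noise <- runif(1, 0, 0.02)
    height <- dh * memphys:::pseudo_voigt(tm, tm, fw, eta = 0)
    tg <- gen_thermogram(tm = tm, dh = dh, fwhm = fw, eta = 0,
                         noise_sd = noise * height,
                         seed = sample.int(1e6, 1))
    tr <- analyze_transition(baseline_correct(tg))
    errs[i, ] <- c(abs(tr$Tm_C - tm), abs(tr$dH_kcal_mol / dh - 1))
  }
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.02)
})

test_that("control-relative summaries reproduce reported shifts", {
  tbl <- data.frame(
    membrane = c("DOPC", "DOPC", "DOPC/DOPS", "DOPC/DOPS"),
    conc = c(0, 40, 0, 40),
    Tm_C = c(-16.68, -17.78, -15.88, -18.98),
    dH_kcal_mol = c(8.34, 5.31, 9.10, 3.30)
  )
  out <- thermo_summary(tbl)
  expect_equal(out$dTm_C, c(0, -1.10, 0, -3.10))
  expect_equal(out$rel_dH[4], 3.30 / 9.10, tolerance = 1e-9)
  expect_equal(out$rel_dH[4], 0.363, tolerance = 1e-3)
  same <- thermo_summary(data.frame(membrane = "x", conc = c(0, 1),
                                    Tm_C = c(-15, -15),
                                    dH_kcal_mol = c(5, 5)))
  expect_equal(same$dTm_C[2], 0)
  expect_error(thermo_summary(tbl[tbl$conc > 0, ]),
               class = "memphys_missing_control")
})
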