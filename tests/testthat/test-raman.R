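test_that("preprocessing flattens the baseline and normalises the 2850 band", {
  sp <- gen_raman_spectrum(conc_mM = 0, seed = 1, noise_sd = 0)
  s <- preprocess_spectrum(sp$spectrum)
  flank <- s$wavenumber_cm1 < 1400 & s$wavenumber_cm1 > 700
  expect_lt(max(abs(s$intensity[flank])), 0.01)
  sel <- s$wavenumber_cm1 >= 2840 & s$wavenumber_cm1 <= 2860
  expect_equal(max(s$intensity[sel]), 1)
})

test_that("preprocessing is idempotent on a clean normalised spectrum", {
  sp <- gen_raman_spectrum(conc_mM = 0, seed = 1, noise_sd = 0,
                           baseline_coefs = c(0, 0, 0, 0))
  s1 <- preprocess_spectrum(sp$spectrum)
  s2 <- preprocess_spectrum(s1)
  expect_equal(s2$intensity, s1$intensity, tolerance = 1e-9)
})

test_that("a flat spectrum is rejected as unusable", {
  flat <- tibble::tibble(wavenumber_cm1 = seq(650, 3450, 1), intensity = 0.3)
  expect_error(preprocess_spectrum(flat), class = "memphys_no_band")
})

test_that("band ratios follow injected band heights", {
  sp <- gen_raman_spectrum(heights = c(1.0, 0.8, 0.5), mix_w = 0,
                           noise_sd = 0, baseline_coefs = c(0, 0, 0, 0))
  r <- ch_stretch_ratios(sp$spectrum)
  expect_equal(r$r_2930_2890, 0.625, tolerance = 1e-6)
  expect_equal(r$r_2930_2850, 0.5, tolerance = 1e-6)
  req <- ch_stretch_ratios(gen_raman_spectrum(heights = c(0.7, 0.7, 0.7),
                                              mix_w = 0, noise_sd = 0,
                                              baseline_coefs = c(0, 0, 0, 0))$spectrum)
  # equal heights: ratios of one up to neighbouring-band tail overlap
  expect_equal(req$r_2930_2890, 1.0, tolerance = 1e-4)
  expect_equal(req$r_2930_2850, 1.0, tolerance = 1e-4)
})

test_that("ratios are invariant under global intensity scaling", {
  sp <- gen_raman_spectrum(conc_mM = 10, seed = 3)
  for (k in c(0.2, 5, 40)) {
    scaled <- sp$spectrum
    scaled$intensity <- k * scaled$intensity
    r0 <- ch_stretch_ratios(preprocess_spectrum(sp$spectrum))
    rk <- ch_stretch_ratios(preprocess_spectrum(scaled))
    expect_equal(rk$r_2930_2890, r0$r_2930_2890, tolerance = 1e-9)
    expect_equal(rk$r_2930_2850, r0$r_2930_2850, tolerance = 1e-9)
  }
})

test_that("relative ratio against a control behaves as a ratio of ratios", {
  s <- preprocess_spectrum(gen_raman_spectrum(conc_mM = 0, seed = 2)$spectrum)
  r <- ch_stretch_ratios(s)
  expect_equal(ch_stretch_ratios(s, control_ratio = r$r_2930_2890)$rel_ratio, 1)
})

test_that("reference subtraction restores the lipid-only spectrum", {
  set.seed(31)
  for (w in c(0.1, 0.3, runif(8))) {
    sp <- gen_raman_spectrum(conc_mM = 10, mix_w = w, seed = 77, noise_sd = 0)
    s <- preprocess_spectrum(sp$spectrum)
    ref <- preprocess_reference(sp$reference)
    out <- subtract_reference(s, ref)
    lip <- preprocess_spectrum(sp$lipid_only)
    ch <- out$wavenumber_cm1 >= 2800 & out$wavenumber_cm1 <= 3000
    expect_lt(max(abs(out$intensity[ch] - lip$intensity[ch])), 0.01)
    r_out <- ch_stretch_ratios(out)$r_2930_2890
    r_lip <- ch_stretch_ratios(lip)$r_2930_2890
    expect_equal(r_out, r_lip, tolerance = 0.01)
  }
})

test_that("subtraction edge cases behave as limits demand", {
  sp <- gen_raman_spectrum(conc_mM = 0, mix_w = 0, seed = 4, noise_sd = 0)
  s <- preprocess_spectrum(sp$spectrum)
  ref <- preprocess_reference(sp$reference)
  # no 1540 band in the sample: scale factor 0, spectrum unchanged
  out <- subtract_reference(s, ref)
  expect_lt(attr(out, "k"), 1e-4)
  expect_equal(out$intensity, s$intensity, tolerance = 1e-3)
  # self-subtraction annihilates the spectrum
  self <- subtract_reference(ref, ref, renormalize = FALSE)
  expect_lt(max(self$intensity), 1e-9)
  # a reference without the indole band is invalid
  bad_ref <- ref
  bad_ref$intensity[bad_ref$wavenumber_cm1 >= 1400 &
                      bad_ref$wavenumber_cm1 <= 1700] <- 0
  expect_error(subtract_reference(s, bad_ref), class = "memphys_no_band")
})

test_that("recovered relative ratio rises monotonically with concentration", {
  ratios <- vapply(c(0, 1, 5, 10, 20, 40), function(conc) {
    sp <- gen_raman_spectrum(conc_mM = conc, seed = 9, noise_sd = 0)
    s <- preprocess_spectrum(sp$spectrum)
    if (conc > 0) s <- subtract_reference(s, preprocess_reference(sp$reference))
    ch_stretch_ratios(s)$r_2930_2890
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  truth <- vapply(c(0, 1, 5, 10, 20, 40), function(conc) {
    attr(gen_raman_spectrum(conc_mM = conc, seed = 9)$spectrum, "ratio_true")
  }, numeric(1))
  expect_equal(ratios, truth, tolerance = 0.01)
})
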