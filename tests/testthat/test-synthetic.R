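test_that("the effect model encodes controls and saturating dose responses", {
  em <- default_effect_model()
  expect_equal(effect_level(em, "DOPC", "pf", 0), 73)
  expect_equal(effect_level(em, "DOPC", "pf", 40), 83)
  expect_equal(effect_level(em, "DOPC/DOPS", "pf", 0), 62)
  expect_equal(effect_level(em, "DOPC/SM/Chol", "tm", 0), -18.67)
  # saturating: increments shrink with concentration
  lv <- effect_level(em, "DOPC", "pf", c(0, 10, 20, 40, 80))
  expect_true(all(diff(lv) > 0))
  expect_true(all(diff(diff(lv)) < 0))
  expect_error(effect_level(em, "DOPC", "nope", 0),
               class = "memphys_bad_label")
  over <- default_effect_model(overrides = data.frame(
    membrane = "DOPC", observable = "pf", control = 70))
  expect_equal(effect_level(over, "DOPC", "pf", 0), 70)
})

test_that("generators are pure functions of parameters and seed", {
  a <- gen_droplet_timeseries(conc_mM = 10, seed = 42)
  b <- gen_droplet_timeseries(conc_mM = 10, seed = 42)
  expect_identical(a$d1_um, b$d1_um)
  expect_false(identical(a$d1_um,
                         gen_droplet_timeseries(conc_mM = 10, seed = 43)$d1_um))
  t1 <- gen_thermogram(conc_mM = 5, seed = 7)
  t2 <- gen_thermogram(conc_mM = 5, seed = 7)
  expect_identical(t1$cp_kcal_mol_C, t2$cp_kcal_mol_C)
  s1 <- gen_raman_spectrum(conc_mM = 5, seed = 7)
  s2 <- gen_raman_spectrum(conc_mM = 5, seed = 7)
  expect_identical(s1$spectrum$intensity, s2$spectrum$intensity)
  d1 <- gen_study_dataset(seed = 3)
  d2 <- gen_study_dataset(seed = 3)
  expect_identical(d1, d2)
  # the generator leaves the global RNG stream untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_thermogram(seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("droplet trace generator round-trips through the estimator", {
  ts <- gen_droplet_timeseries(membrane = "DOPC", conc_mM = 0, seed = 1,
                               radius_noise_cv = 0)
  expect_equal(attr(ts, "pf_true"), 73)
  fit <- estimate_pf(ts)
  expect_equal(fit$pf_um_s, 73, tolerance = 0.01)
})

test_that("thermogram generator injects its ground truth and dose trend", {
  tg <- gen_thermogram(membrane = "DOPC", conc_mM = 0, seed = 1)
  expect_equal(attr(tg, "tm_true"), -16.68)
  expect_equal(attr(tg, "dh_true"), 8.34)
  expect_equal(attr(tg, "fwhm_true"), 1.5)
  tg0 <- gen_thermogram(membrane = "DOPC", conc_mM = 0, noise_sd = 0)
  tr <- analyze_transition(baseline_correct(tg0))
  expect_equal(tr$Tm_C, -16.68, tolerance = 0.05 / 16)
  expect_equal(tr$dH_kcal_mol, 8.34, tolerance = 0.02)
  expect_equal(tr$fwhm_C, 1.5, tolerance = 0.03)
  tms <- vapply(c(0, 5, 20, 40),
                function(cc) attr(gen_thermogram(conc_mM = cc), "tm_true"),
                numeric(1))
  dhs <- vapply(c(0, 5, 20, 40),
                function(cc) attr(gen_thermogram(conc_mM = cc), "dh_true"),
                numeric(1))
  expect_true(all(diff(tms) < 0))
  expect_true(all(diff(dhs) < 0))
})

test_that("raman generator ground truth covers the control and mixtures", {
  sp0 <- gen_raman_spectrum(conc_mM = 0, seed = 2)
  em <- default_effect_model()
  expect_equal(attr(sp0$spectrum, "ratio_true"),
               em$control[em$membrane == "DOPC" & em$observable == "ratio"])
  expect_equal(attr(sp0$spectrum, "mix_w"), 0)
  sp40 <- gen_raman_spectrum(conc_mM = 40, seed = 2)
  expect_gt(attr(sp40$spectrum, "ratio_true"),
            attr(sp0$spectrum, "ratio_true"))
})

test_that("the study table covers the factorial design with its truth", {
  d <- gen_study_dataset(n_replicates = 3, seed = 1)
  expect_equal(nrow(d), 3 * 6 * 3 * 7)
  expect_setequal(unique(d$observable),
                  c("pf", "tm", "dh", "fwhm", "ratio", "gamma_m", "theta"))
  expect_true(all(table(d$membrane, d$conc) == 21))
  pf40 <- d[d$observable == "pf" & d$conc == 40, ]
  expect_equal(unique(pf40$true_mean[pf40$membrane == "DOPC"]), 83)
  # per-observable replicate counts mirror pooled vs per-sample designs
  d2 <- gen_study_dataset(n_replicates = c(pf = 10, tm = 3), seed = 1,
                          observables = c("pf", "tm"))
  expect_equal(sum(d2$observable == "pf"), 18 * 10)
  expect_equal(sum(d2$observable == "tm"), 18 * 3)
})

test_that("droplet image generator records its ground-truth circles", {
  img <- gen_droplet_image(r1 = 40, r2 = 30, d = 60, noise_sd = 0)
  truth <- attr(img, "circles")
  expect_equal(truth$r, c(40, 30))
  expect_true(is.matrix(img))
  expect_error(gen_droplet_image(r1 = -1, r2 = 30, d = 60))
  img2 <- gen_droplet_image(r1 = 40, r2 = 30, d = 60, noise_sd = 0.05,
                            seed = 5)
  expect_identical(img2, gen_droplet_image(r1 = 40, r2 = 30, d = 60,
                                           noise_sd = 0.05, seed = 5))
})
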