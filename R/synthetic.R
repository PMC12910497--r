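# Seeded synthetic-data generators.
#
# The generators emulate the raw instrument outputs the analysis chains
# consume: DIB droplet shrink/swell traces, droplet-pair micrographs, DSC
# endotherms and Raman spectra, organised as a 3-membrane x 6-concentration
# factorial study. Every generated object carries its ground truth so
# round-trip recovery is the universal test pattern. All generators are pure
# functions of (parameters, seed).

MEMBRANES <- c("DOPC", "DOPC/DOPS", "DOPC/SM/Chol")
CONC_LEVELS_MM <- c(0, 1, 5, 10, 20, 40)

#' Dose-response effect model for the synthetic study
#'
#' Control levels and saturating dose-response amplitudes for each
#' observable of each membrane model. Effects saturate as
#' \eqn{\mathrm{value}(c) = \mathrm{control} + \mathrm{amp}\, c / (c +
#' c_{50})}, mimicking the levelling-off of membrane modification at high
#' guest-molecule concentration; `amp` is chosen so the 40 mM (molar ratio
#' 4:1) condition reproduces the study's end-point values, and `c50`
#' defaults to 10 mM, where effects become prominent. Control levels are the
#' measured control values of each chain; the Raman ratio controls and the
#' DOPC/DOPS tensiometry column are illustrative, as those controls are not
#' tabulated. Noise entries are per-replicate SDs (`noise_type "cv"` =
#' coefficient of variation, `"sd"` = absolute).
#'
#' @param c50_mM Half-saturation concentration shared by all observables.
#' @param overrides Optional data frame with columns `membrane`,
#'   `observable` and any of `control`, `amp`, `noise`, replacing the
#'   matching default rows.
#' @return An `effect_model`: a tibble with columns `membrane`,
#'   `observable`, `control`, `amp`, `noise`, `noise_type` and attribute
#'   `c50_mM`.
#' @examples
#' default_effect_model()
#' @export
default_effect_model <- function(c50_mM = 10, overrides = NULL) {
  base <- tibble::tribble(
    ~membrane,       ~observable, ~control, ~amp,     ~noise, ~noise_type,
    "DOPC",          "pf",          73,      12.5,     0.03,  "cv",
    "DOPC/DOPS",     "pf",          62,      15.0,     0.03,  "cv",
    "DOPC/SM/Chol",  "pf",          67,      16.25,    0.03,  "cv",
    "DOPC",          "tm",         -16.68,   -1.375,   0.10,  "sd",
    "DOPC/DOPS",     "tm",         -15.88,   -3.875,   0.10,  "sd",
    "DOPC/SM/Chol",  "tm",         -18.67,   -7.3375,  0.10,  "sd",
    "DOPC",          "dh",           8.34,   -3.7875,  0.05,  "cv",
    "DOPC/DOPS",     "dh",           9.10,   -7.25,    0.05,  "cv",
    "DOPC/SM/Chol",  "dh",           2.67,   -2.775,   0.05,  "cv",
    "DOPC",          "fwhm",         1.50,    1.2625,  0.05,  "cv",
    "DOPC/DOPS",     "fwhm",         0.95,    3.4875,  0.05,  "cv",
    "DOPC/SM/Chol",  "fwhm",         2.73,    3.4625,  0.05,  "cv",
    "DOPC",          "ratio",        0.85,    0.1275,  0.03,  "cv",
    "DOPC/DOPS",     "ratio",        0.80,    0.28,    0.03,  "cv",
    "DOPC/SM/Chol",  "ratio",        0.75,    0.2625,  0.03,  "cv",
    "DOPC",          "gamma_m",      1.125,  -0.57625, 0.02,  "cv",
    "DOPC/DOPS",     "gamma_m",      1.15,   -0.75,    0.02,  "cv",
    "DOPC/SM/Chol",  "gamma_m",      1.185,  -0.94625, 0.02,  "cv",
    "DOPC",          "theta",       31.20,   21.8875,  0.30,  "sd",
    "DOPC/DOPS",     "theta",       30.00,   18.00,    0.30,  "sd",
    "DOPC/SM/Chol",  "theta",       23.96,   14.9875,  0.30,  "sd"
  )
  if (!is.null(overrides)) {
    stopifnot(all(c("membrane", "observable") %in% names(overrides)))
    for (i in seq_len(nrow(overrides))) {
      j <- which(base$membrane == overrides$membrane[i] &
                   base$observable == overrides$observable[i])
      for (col in intersect(names(overrides), c("control", "amp", "noise"))) {
        if (!is.na(overrides[[col]][i])) base[[col]][j] <- overrides[[col]][i]
      }
    }
  }
  structure(base, c50_mM = c50_mM, class = c("effect_model", class(base)))
}

#' Expected (noise-free) observable value under an effect model
#'
#' @param em Effect model from [default_effect_model()].
#' @param membrane,observable Row selectors.
#' @param conc_mM Concentration(s), mM.
#' @return Numeric vector of expected values.
#' @export
effect_level <- function(em, membrane, observable, conc_mM) {
  row <- em[em$membrane == membrane & em$observable == observable, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown membrane/observable pair: %s / %s.",
                  membrane, observable), class = "memphys_bad_label")
  }
  c50 <- attr(em, "c50_mM")
  row$control + row$amp * conc_mM / (conc_mM + c50)
}

effect_noise_sd <- function(em, membrane, observable, mean_value) {
  row <- em[em$membrane == membrane & em$observable == observable, ]
  if (row$noise_type == "cv") abs(mean_value) * row$noise else row$noise
}

#' Generate a synthetic DIB droplet shrink/swell trace
#'
#' Forward-simulates the osmotic transport model with the effect model's
#' permeability for the requested condition, then applies multiplicative
#' radius noise (`d_obs = d_true * (1 + e)`, `e ~ N(0, radius_noise_cv)`,
#' independent per frame and droplet). The ground-truth permeability is
#' stored in attribute `pf_true`.
#'
#' @param em Effect model; default [default_effect_model()].
#' @param membrane One of `"DOPC"`, `"DOPC/DOPS"`, `"DOPC/SM/Chol"`.
#' @param conc_mM Guest-molecule concentration, mM.
#' @param seed Integer seed; generators are pure functions of their
#'   arguments and the seed.
#' @param radius_noise_cv Multiplicative radius noise SD (0.005 = 0.5%).
#' @param duration_s,dt_s Observation window and frame interval, seconds.
#' @param pf_um_s Override the effect-model permeability (e.g. to add
#'   run-to-run variation).
#' @inheritParams simulate_osmosis
#' @return A `droplet_timeseries` tibble (see [simulate_osmosis()]).
#' @export
gen_droplet_timeseries <- function(em = default_effect_model(),
                                   membrane = "DOPC", conc_mM = 0, seed = 1,
                                   radius_noise_cv = 0.005,
                                   duration_s = 60, dt_s = 1,
                                   d1_um = 100, d2_um = 100,
                                   osmolality_hyper = 186, theta_deg = 31.2,
                                   pf_um_s = NULL) {
  pf <- pf_um_s %||% effect_level(em, membrane, "pf", conc_mM)
  ts <- simulate_osmosis(pf = pf, times = seq(0, duration_s, by = dt_s),
                         d1_um = d1_um, d2_um = d2_um,
                         osmolality_hyper = osmolality_hyper,
                         theta_deg = theta_deg)
  if (radius_noise_cv > 0) {
    withr_seed(seed, {
      ts$d1_um <- ts$d1_um * (1 + rnorm(nrow(ts), 0, radius_noise_cv))
      ts$d2_um <- ts$d2_um * (1 + rnorm(nrow(ts), 0, radius_noise_cv))
    })
  }
  attr(ts, "pf_true") <- pf
  attr(ts, "membrane") <- membrane
  attr(ts, "conc_mM") <- conc_mM
  ts
}

# local seed scope without external deps
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# unit-area pseudo-Voigt profile: eta Lorentzian + (1 - eta) Gaussian,
# common fwhm
pseudo_voigt <- function(x, center, fwhm, eta = 0.2) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gam <- fwhm / 2
  g <- exp(-(x - center)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  l <- gam / (pi * ((x - center)^2 + gam^2))
  eta * l + (1 - eta) * g
}

#' Generate a synthetic DSC endotherm
#'
#' A single pseudo-Voigt endothermic peak with the effect model's (or
#' explicitly given) transition temperature, enthalpy and width, on a gentle
#' linear baseline, plus seeded Gaussian noise. Ground truth is attached as
#' attributes `tm_true`, `dh_true`, `fwhm_true`.
#'
#' @inheritParams gen_droplet_timeseries
#' @param tm,dh,fwhm Override the effect-model transition temperature
#'   (degC), enthalpy (kcal/mol) and peak width (degC).
#' @param T_range,dT Scan window (degC) and grid step.
#' @param eta Lorentzian fraction of the pseudo-Voigt profile.
#' @param baseline_intercept,baseline_slope Linear instrumental baseline
#'   (kcal mol^-1 degC^-1 at 0 degC, and per degC).
#' @param noise_sd Additive noise SD in cp units; default 1% of peak height.
#' @return A thermogram tibble (`T_C`, `cp_kcal_mol_C`) with ground-truth
#'   attributes.
#' @export
gen_thermogram <- function(em = default_effect_model(), membrane = "DOPC",
                           conc_mM = 0, seed = 1,
                           tm = NULL, dh = NULL, fwhm = NULL,
                           T_range = c(-40, -5), dT = 0.05, eta = 0.2,
                           baseline_intercept = 0.05, baseline_slope = 0.01,
                           noise_sd = NULL) {
  tm <- tm %||% effect_level(em, membrane, "tm", conc_mM)
  dh <- dh %||% effect_level(em, membrane, "dh", conc_mM)
  fwhm <- fwhm %||% effect_level(em, membrane, "fwhm", conc_mM)
  T_C <- seq(T_range[1], T_range[2], by = dT)
  peak <- dh * pseudo_voigt(T_C, tm, fwhm, eta)
  height <- max(peak)
  noise_sd <- noise_sd %||% (0.01 * height)
  baseline <- baseline_intercept + baseline_slope * (T_C - T_range[1])
  cp <- peak + baseline
  if (noise_sd > 0) {
    withr_seed(seed, cp <- cp + rnorm(length(cp), 0, noise_sd))
  }
  structure(tibble::tibble(T_C = T_C, cp_kcal_mol_C = cp),
            tm_true = tm, dh_true = dh, fwhm_true = fwhm,
            membrane = membrane, conc_mM = conc_mM,
            scan_rate_C_min = 5, direction = "heating")
}

gaussian_band <- function(x, center, height, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(x - center)^2 / (2 * sigma^2))
}

#' Generate a synthetic Raman spectrum with its guest reference
#'
#' The lipid contribution is three Gaussian C-H stretching bands at 2850,
#' 2890 and 2930 cm^-1 whose heights follow the effect model: with rising
#' concentration the 2930 band grows and the 2890 band falls, so the
#' 2930/2890 ratio rises along the saturating dose-response. The guest
#' (serotonin-like) reference carries the 1540 cm^-1 indole band plus a
#' small C-H region contribution at 2930 cm^-1; the sample is
#' `lipid + w * reference` with mixing weight `w` proportional to
#' concentration. Both sample and reference sit on sloped baselines with
#' seeded noise. Ground-truth band heights and ratios are attached as
#' attributes (`ratio_true` = lipid-only 2930/2890 ratio).
#'
#' @inheritParams gen_droplet_timeseries
#' @param heights Optional explicit lipid band heights
#'   `c(h2850, h2890, h2930)`, overriding the effect model.
#' @param mix_w Optional explicit guest mixing weight (default
#'   `0.4 * conc / 40`).
#' @param wn_range,dwn Wavenumber grid range and step, cm^-1.
#' @param band_fwhm Common band width, cm^-1.
#' @param baseline_coefs Cubic baseline coefficients (applied to the
#'   wavenumber scaled to `[0, 1]`).
#' @param noise_sd Additive intensity noise SD (a.u.); lipid 2850 height
#'   is 1.
#' @return A list with elements `spectrum`, `reference` and `lipid_only`,
#'   each a spectrum tibble; ground truth rides on `spectrum`'s attributes.
#' @export
gen_raman_spectrum <- function(em = default_effect_model(),
                               membrane = "DOPC", conc_mM = 0, seed = 1,
                               heights = NULL, mix_w = NULL,
                               wn_range = c(650, 3450), dwn = 1,
                               band_fwhm = 18,
                               baseline_coefs = c(0.05, 0.08, -0.04, 0.02),
                               noise_sd = 0.002) {
  wn <- seq(wn_range[1], wn_range[2], by = dwn)
  if (is.null(heights)) {
    # drive the 2930/2890 ratio along the dose-response, split evenly
    # between a rising 2930 and a falling 2890 band
    r0 <- em$control[em$membrane == membrane & em$observable == "ratio"]
    r <- effect_level(em, membrane, "ratio", conc_mM)
    f <- sqrt(r / r0)
    h2890 <- 0.80 / f
    heights <- c(1.0, h2890, r * h2890)
  }
  stopifnot(length(heights) == 3, all(heights >= 0))
  lipid <- gaussian_band(wn, 2850, heights[1], band_fwhm) +
    gaussian_band(wn, 2890, heights[2], band_fwhm) +
    gaussian_band(wn, 2930, heights[3], band_fwhm)
  ref_shape <- gaussian_band(wn, 1540, 1.0, 16) +
    gaussian_band(wn, 2930, 0.12, band_fwhm)
  w <- mix_w %||% (0.4 * conc_mM / 40)
  u <- (wn - wn_range[1]) / diff(wn_range)
  base_s <- drop(cbind(1, u, u^2, u^3) %*% baseline_coefs)
  sample_int <- lipid + w * ref_shape + base_s
  ref_int <- ref_shape + 0.5 * base_s
  if (noise_sd > 0) {
    withr_seed(seed, {
      sample_int <- sample_int + rnorm(length(wn), 0, noise_sd)
      ref_int <- ref_int + rnorm(length(wn), 0, noise_sd)
    })
  }
  spectrum <- tibble::tibble(wavenumber_cm1 = wn, intensity = sample_int)
  attr(spectrum, "heights_true") <- heights
  attr(spectrum, "ratio_true") <- heights[3] / heights[2]
  attr(spectrum, "mix_w") <- w
  attr(spectrum, "membrane") <- membrane
  attr(spectrum, "conc_mM") <- conc_mM
  list(
    spectrum = spectrum,
    reference = tibble::tibble(wavenumber_cm1 = wn, intensity = ref_int),
    lipid_only = tibble::tibble(wavenumber_cm1 = wn, intensity = lipid)
  )
}

#' Generate the factorial study table
#'
#' Draws replicated observable values for the full 3-membrane x
#' 6-concentration design directly from the effect model (expected value
#' plus Gaussian replicate noise). This is the input for the statistics
#' layer; the per-chain generators ([gen_droplet_timeseries()],
#' [gen_thermogram()], [gen_raman_spectrum()]) produce the corresponding
#' raw instrument records.
#'
#' @inheritParams gen_droplet_timeseries
#' @param n_replicates Replicates per cell: a single number, or a named
#'   vector per observable (e.g. `c(pf = 50, tm = 3)`), mirroring designs
#'   that pool many permeability runs but few calorimetry samples.
#' @param observables Which observables to draw.
#' @param conc_mM Concentration levels of the design.
#' @return A tidy tibble: `membrane`, `conc`, `replicate`, `observable`,
#'   `value`, `true_mean`.
#' @export
gen_study_dataset <- function(em = default_effect_model(), n_replicates = 3,
                              seed = 1,
                              observables = c("pf", "tm", "dh", "fwhm",
                                              "ratio", "gamma_m", "theta"),
                              conc_mM = CONC_LEVELS_MM) {
  reps_for <- function(obs) {
    if (length(n_replicates) == 1 && is.null(names(n_replicates))) {
      as.integer(n_replicates)
    } else {
      as.integer(n_replicates[[obs]] %||% 3L)
    }
  }
  grid <- tidyr::expand_grid(membrane = MEMBRANES, conc = conc_mM,
                             observable = observables)
  withr_seed(seed, {
    out <- purrr::pmap_dfr(grid, function(membrane, conc, observable) {
      mu <- effect_level(em, membrane, observable, conc)
      sdv <- effect_noise_sd(em, membrane, observable, mu)
      nr <- reps_for(observable)
      tibble::tibble(membrane = membrane, conc = conc,
                     replicate = seq_len(nr), observable = observable,
                     value = rnorm(nr, mu, sdv), true_mean = mu)
    })
  })
  out
}

#' Draw a synthetic droplet-pair micrograph
#'
#' Renders two bright anti-aliased disks on a dark background (raster
#' convention: origin top-left, x rightward, y downward, pixels), optionally
#' with additive Gaussian noise, as a fixture for [detect_droplet_pair()].
#'
#' @param r1,r2 Disk radii, px.
#' @param d Centre separation, px; the pair is horizontal and centred.
#' @param width,height Image size, px.
#' @param fg,bg Foreground/background intensity.
#' @param noise_sd Additive noise SD as a fraction of the dynamic range.
#' @param seed Seed for the noise draw.
#' @return A numeric intensity matrix (rows = y), with ground truth in
#'   attribute `circles` (tibble `cx`, `cy`, `r`).
#' @export
gen_droplet_image <- function(r1 = 50, r2 = 50, d = 87,
                              width = NULL, height = NULL,
                              fg = 1, bg = 0, noise_sd = 0, seed = 1) {
  stopifnot(r1 > 0, r2 > 0, d > 0)
  width <- width %||% ceiling(d + 2 * (r1 + r2) + 40)
  height <- height %||% ceiling(2 * max(r1, r2) + 40)
  cy <- height / 2
  cx1 <- (width - d) / 2
  cx2 <- cx1 + d
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  # anti-aliased edge: ~1 px linear ramp
  disk <- function(cx, cyy, r) {
    dist <- sqrt((xs - cx)^2 + (ys - cyy)^2)
    pmin(pmax(r + 0.5 - dist, 0), 1)
  }
  img <- bg + (fg - bg) * pmax(disk(cx1, cy, r1), disk(cx2, cy, r2))
  if (noise_sd > 0) {
    withr_seed(seed, {
      img <- img + rnorm(length(img), 0, noise_sd * abs(fg - bg))
    })
  }
  attr(img, "circles") <- tibble::tibble(cx = c(cx1, cx2), cy = cy,
                                         r = c(r1, r2))
  img
}
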