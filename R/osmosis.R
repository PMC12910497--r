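# Osmotic water transport across a droplet interface bilayer.
#
# Model: two monolayer-coated droplets share a bilayer of area A. Solutes are
# impermeant (ion permeation is orders of magnitude slower than water), so
# each droplet's osmotically active content n_i is constant and its
# osmolarity is c_i = n_i / V_i. Water volume flux follows the standard
# osmotic-permeability definition
#
#   dV1/dt = Pf * Vw * A * (c1 - c2),   dV2/dt = -dV1/dt
#
# with Pf the osmotic water permeability (um/s) and Vw the molar volume of
# water. Droplet 1 is the solute (hyperosmotic) droplet and swells; its
# partner shrinks. All internal lengths are micrometres, times seconds.

MOLAR_VOLUME_WATER_CM3_MOL <- 18.05 # ~30 degC

# mOsm/kg solvent -> osmol per um^3 of solution (density in kg/L)
osmolality_to_conc <- function(osmolality_mOsm_kg, density_kg_L = 1.0) {
  osmolality_mOsm_kg * 1e-3 * density_kg_L / 1e15
}

#' Forward-simulate osmotic water transport across a DIB
#'
#' Integrates the two-droplet osmotic volume-flux model with an adaptive
#' solver (deSolve, relative tolerance `rtol`) and returns the droplet
#' diameter time series. Droplets are treated as full spheres (the
#' spherical-cap volume correction for the small contact patch is ignored).
#'
#' @param pf Osmotic water permeability coefficient, um/s. Must be positive.
#' @param times Increasing time grid, seconds.
#' @param d1_um,d2_um Initial diameters (um) of the solute (hyperosmotic)
#'   droplet and its partner.
#' @param osmolality_hyper Initial osmolality of the solute droplet,
#'   mOsm/kg. The default 186 corresponds to nominally 0.1 M NaCl (ideal
#'   van 't Hoff factor 2 corrected by an osmotic coefficient of 0.93);
#'   override with the measured osmolality whenever available.
#' @param osmolality_partner Initial osmolality of the partner droplet
#'   (default 0, pure water).
#' @param area_um2 Bilayer contact area, um^2. If `NULL` it is computed from
#'   `theta_deg` as \eqn{\pi (R \sin\theta)^2} with `R` the smaller initial
#'   droplet radius.
#' @param theta_deg Contact angle used when `area_um2` is `NULL` and, with
#'   `dynamic_area = TRUE`, to recompute the area along the trajectory at
#'   constant angle. Default 30.
#' @param dynamic_area If `TRUE`, the bilayer area follows the shrinking
#'   droplet at constant contact angle; default `FALSE` (constant area,
#'   appropriate for short observation windows).
#' @param vw_cm3_mol Molar volume of water, cm^3/mol.
#' @param density_kg_L Solution density used to convert osmolality to
#'   osmolarity; default 1.0.
#' @param temperature_C Recorded temperature (metadata only; the model has
#'   no explicit temperature dependence).
#' @param rtol Relative tolerance of the integrator.
#' @return A tibble of class `droplet_timeseries` with columns `t_s`,
#'   `d1_um`, `d2_um`, `A_um2`, carrying the simulation settings as
#'   attributes (`osmolality_hyper`, `osmolality_partner`, `pf_true`, ...).
#'   If a droplet volume reaches zero the series is truncated at the
#'   depletion time (attribute `truncated_at`, with a warning).
#' @examples
#' ts <- simulate_osmosis(pf = 73, times = 0:60)
#' head(ts)
#' @export
simulate_osmosis <- function(pf, times, d1_um = 100, d2_um = 100,
                             osmolality_hyper = 186, osmolality_partner = 0,
                             area_um2 = NULL, theta_deg = 30,
                             dynamic_area = FALSE,
                             vw_cm3_mol = MOLAR_VOLUME_WATER_CM3_MOL,
                             density_kg_L = 1.0, temperature_C = 30,
                             rtol = 1e-8) {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  if (!is.numeric(pf) || length(pf) != 1 || pf <= 0) {
    abort("`pf` must be a single positive number.", class = "memphys_bad_measurement")
  }
  V0 <- c(sphere_volume_from_diameter(d1_um), sphere_volume_from_diameter(d2_um))
  conc0 <- c(osmolality_to_conc(osmolality_hyper, density_kg_L),
             osmolality_to_conc(osmolality_partner, density_kg_L))
  n_osm <- conc0 * V0                      # constant solute content, osmol
  vw_um3 <- vw_cm3_mol * 1e12              # um^3 per mol
  sin_th <- sin(theta_deg * pi / 180)
  area_fun <- if (dynamic_area) {
    function(V) {
      rmin <- min((6 * V / pi)^(1 / 3)) / 2
      pi * (rmin * sin_th)^2
    }
  } else {
    A0 <- area_um2 %||% (pi * (min(d1_um, d2_um) / 2 * sin_th)^2)
    function(V) A0
  }
  deriv <- function(t, V, parms) {
    flux <- pf * vw_um3 * area_fun(V) * (n_osm[1] / V[1] - n_osm[2] / V[2])
    list(c(flux, -flux))
  }
  root <- function(t, V, parms) min(V) - 1e-6 * min(V0)
  sol <- deSolve::ode(y = V0, times = times, func = deriv, parms = NULL,
                      method = "lsodar", rtol = rtol,
                      atol = rtol * min(V0), rootfunc = root)
  sol <- as.data.frame(sol)
  truncated_at <- NULL
  if (nrow(sol) < length(times)) {
    truncated_at <- sol$time[nrow(sol)]
    warn(sprintf("Droplet depleted: trajectory truncated at t = %.3g s.",
                 truncated_at))
  }
  V1 <- sol[[2]]; V2 <- sol[[3]]
  out <- tibble::tibble(
    t_s = sol$time,
    d1_um = sphere_diameter_from_volume(V1),
    d2_um = sphere_diameter_from_volume(V2),
    A_um2 = vapply(seq_along(V1), function(i) area_fun(c(V1[i], V2[i])), numeric(1))
  )
  structure(out,
            class = c("droplet_timeseries", class(out)),
            osmolality_hyper = osmolality_hyper,
            osmolality_partner = osmolality_partner,
            density_kg_L = density_kg_L,
            vw_cm3_mol = vw_cm3_mol,
            theta_deg = theta_deg,
            dynamic_area = dynamic_area,
            temperature_C = temperature_C,
            pf_true = pf,
            truncated_at = truncated_at)
}

#' Estimate the osmotic water permeability coefficient from a droplet trace
#'
#' Two estimators for \eqn{P_f} from a DIB shrink/swell diameter time
#' series:
#'
#' * `initial_rate` — linear fit of droplet volume over an initial window
#'   (the larger of 10 frames and 10% of the series), averaging the swell
#'   and shrink slopes; \eqn{P_f = (dV/dt)_0 / (V_w A \Delta c_0)}.
#' * `ode_fit` — bounded least-squares fit of the forward model
#'   ([simulate_osmosis()]) to both observed diameter traces, with the
#'   initial-rate estimate as starting value.
#'
#' @param ts A `droplet_timeseries` (from [simulate_osmosis()], a generator,
#'   or [read_droplet_timeseries()]): columns `t_s`, `d1_um`, `d2_um` and
#'   optionally `A_um2`; droplet 1 is the solute droplet.
#' @param method `"ode_fit"` (default) or `"initial_rate"`.
#' @param area_um2 Bilayer area; defaults to the series' `A_um2` column.
#' @param osmolality_hyper,osmolality_partner Initial osmolalities
#'   (mOsm/kg); default from the series attributes.
#' @param pf_max Upper search bound for the fit, um/s.
#' @inheritParams simulate_osmosis
#' @return A `pf_fit` object; see [tidy.pf_fit()] and [glance.pf_fit()].
#'   The point estimate is in element `pf_um_s`.
#' @examples
#' ts <- simulate_osmosis(pf = 73, times = 0:60)
#' estimate_pf(ts)
#' @export
estimate_pf <- function(ts, method = c("ode_fit", "initial_rate"),
                        area_um2 = NULL, osmolality_hyper = NULL,
                        osmolality_partner = NULL,
                        vw_cm3_mol = NULL, density_kg_L = NULL,
                        pf_max = 1e4, rtol = 1e-8) {
  method <- match.arg(method)
  stopifnot(is.data.frame(ts), all(c("t_s", "d1_um", "d2_um") %in% names(ts)))
  n <- nrow(ts)
  if (n < 5) abort("At least 5 frames are required.", class = "memphys_bad_measurement")
  osmolality_hyper <- osmolality_hyper %||% attr(ts, "osmolality_hyper")
  osmolality_partner <- osmolality_partner %||% attr(ts, "osmolality_partner") %||% 0
  if (is.null(osmolality_hyper)) {
    abort("Initial osmolality of the solute droplet is required (argument or series attribute).")
  }
  vw_cm3_mol <- vw_cm3_mol %||% attr(ts, "vw_cm3_mol") %||% MOLAR_VOLUME_WATER_CM3_MOL
  density_kg_L <- density_kg_L %||% attr(ts, "density_kg_L") %||% 1.0
  area_um2 <- area_um2 %||% ts$A_um2[1]
  if (is.null(area_um2) || !is.finite(area_um2) || area_um2 <= 0) {
    abort("A positive bilayer area is required (argument or `A_um2` column).")
  }
  vw_um3 <- vw_cm3_mol * 1e12
  t <- ts$t_s
  V1 <- sphere_volume_from_diameter(ts$d1_um)
  V2 <- sphere_volume_from_diameter(ts$d2_um)
  c0 <- osmolality_to_conc(c(osmolality_hyper, osmolality_partner), density_kg_L)
  dc0 <- c0[1] - c0[2] # initial gradient, osmol/um^3
  if (abs(dc0) <= 0) {
    abort("No initial osmotic gradient: Pf is not identifiable.",
          class = "memphys_not_identifiable")
  }
  # initial-rate estimate over the quasi-linear opening window
  n_win <- min(n, max(10L, ceiling(0.1 * n)))
  idx <- seq_len(n_win)
  slope <- (coef(lm(V1[idx] ~ t[idx]))[[2]] - coef(lm(V2[idx] ~ t[idx]))[[2]]) / 2
  rel_change <- (max(V1) - min(V1)) / V1[1]
  if (rel_change < 1e-12) {
    abort("Flat trace with a nonzero osmotic gradient: measurement failure.",
          class = "memphys_not_identifiable")
  }
  pf_ir <- slope / (vw_um3 * area_um2 * dc0)
  if (method == "initial_rate") {
    if (pf_ir <= 0) {
      abort("Estimated Pf is non-positive: trace is inconsistent with the stated gradient.",
            class = "memphys_inconsistent")
    }
    pf_hat <- pf_ir
    resid <- NA_real_
  } else {
    # start the bounded fit from a whole-trace slope, which is far less
    # noise-sensitive than the short opening window
    slope_full <- (coef(lm(V1 ~ t))[[2]] - coef(lm(V2 ~ t))[[2]]) / 2
    pf0 <- slope_full / (vw_um3 * area_um2 * dc0)
    if (pf0 <= 0) {
      abort("Estimated Pf is non-positive: trace is inconsistent with the stated gradient.",
            class = "memphys_inconsistent")
    }
    # initial volumes from quadratic-trend intercepts: frame-level radius
    # noise on the first frame alone would otherwise offset the whole
    # simulated trajectory by an amount comparable to the osmotic signal
    t0 <- t - t[1]
    d1_0 <- sphere_diameter_from_volume(coef(lm(V1 ~ poly(t0, 2, raw = TRUE)))[[1]])
    d2_0 <- sphere_diameter_from_volume(coef(lm(V2 ~ poly(t0, 2, raw = TRUE)))[[1]])
    simulate_at <- function(pf) {
      suppressWarnings(simulate_osmosis(
        pf = pf, times = t, d1_um = d1_0, d2_um = d2_0,
        osmolality_hyper = osmolality_hyper,
        osmolality_partner = osmolality_partner,
        area_um2 = area_um2, dynamic_area = FALSE,
        vw_cm3_mol = vw_cm3_mol, density_kg_L = density_kg_L, rtol = rtol))
    }
    objective <- function(pf) {
      sim <- simulate_at(pf)
      if (nrow(sim) < n) return(1e12 * (1 + pf)) # depleted before the window end
      sum((sim$d1_um - ts$d1_um)^2 + (sim$d2_um - ts$d2_um)^2)
    }
    lo <- max(1e-3, pf0 / 20)
    hi <- min(pf_max, pf0 * 20)
    opt <- optimize(objective, interval = c(lo, hi),
                    tol = max(1e-8, pf0 * 1e-7))
    pf_hat <- opt$minimum
    resid <- sqrt(opt$objective / (2 * n))
  }
  structure(
    list(pf_um_s = pf_hat, method = method,
         residual = resid, pf_initial_rate = pf_ir,
         n_frames = n, area_um2 = area_um2,
         dc0_osm_um3 = dc0,
         osmolality_hyper = osmolality_hyper,
         osmolality_partner = osmolality_partner),
    class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf("<pf_fit> Pf = %.4g um/s (%s, %d frames", x$pf_um_s, x$method,
              x$n_frames))
  if (is.finite(x$residual %||% NA_real_)) {
    cat(sprintf(", RMS diameter residual %.3g um", x$residual))
  }
  cat(")\n")
  invisible(x)
}

#' Tidy a permeability fit
#'
#' @param x A `pf_fit` object from [estimate_pf()].
#' @param ... Unused.
#' @return One row per estimated term (`Pf`), with `estimate` in um/s.
#' @method tidy pf_fit
#' @export
tidy.pf_fit <- function(x, ...) {
  tibble::tibble(term = "Pf", estimate = x$pf_um_s, unit = "um/s",
                 method = x$method)
}

#' One-row summary of a permeability fit
#'
#' @inheritParams tidy.pf_fit
#' @return A one-row tibble with the estimate, method, residual and sizes.
#' @method glance pf_fit
#' @export
glance.pf_fit <- function(x, ...) {
  tibble::tibble(pf_um_s = x$pf_um_s, method = x$method,
                 residual = x$residual, pf_initial_rate = x$pf_initial_rate,
                 n_frames = x$n_frames, area_um2 = x$area_um2)
}
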