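# Tidy readers/writers for the instrument CSV formats and their JSON
# metadata sidecars. A sidecar for `foo.csv` is `foo.json` in the same
# directory; its fields become attributes of the returned tibble.

read_sidecar <- function(path) {
  side <- sub("\\.csv$", ".json", path)
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
}

apply_meta <- function(x, meta, map) {
  for (nm in names(map)) {
    if (!is.null(meta[[nm]])) attr(x, map[[nm]]) <- meta[[nm]]
  }
  x
}

#' Read a droplet-pair diameter time series
#'
#' CSV columns `t_s`, `d1_um`, `d2_um` and optionally `A_um2`; the JSON
#' sidecar may carry `osmolality_mOsm_kg`, `osmolality_partner_mOsm_kg`,
#' `temperature_C` and `theta_deg`, which become series attributes used by
#' [estimate_pf()].
#'
#' @param path CSV path.
#' @return A `droplet_timeseries` tibble.
#' @export
read_droplet_timeseries <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("t_s", "d1_um", "d2_um") %in% names(x)))
  x <- apply_meta(x, read_sidecar(path),
                  c(osmolality_mOsm_kg = "osmolality_hyper",
                    osmolality_partner_mOsm_kg = "osmolality_partner",
                    temperature_C = "temperature_C",
                    theta_deg = "theta_deg"))
  class(x) <- c("droplet_timeseries", class(x))
  x
}

#' Read a DSC thermogram
#'
#' CSV columns `T_C`, `cp_kcal_mol_C`; sidecar fields `scan_rate_C_min`,
#' `direction`, `lipid_mol`, `molar_ratio` become attributes. Cooling scans
#' (`direction: "cooling"`) have their heat-flow sign flipped so the
#' transition is analysed as an endotherm.
#'
#' @param path CSV path.
#' @return A thermogram tibble.
#' @export
read_thermogram <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x <- as_thermogram(x)
  meta <- read_sidecar(path)
  x <- apply_meta(x, meta, c(scan_rate_C_min = "scan_rate_C_min",
                             direction = "direction", lipid_mol = "lipid_mol",
                             molar_ratio = "molar_ratio"))
  if (identical(meta$direction, "cooling")) {
    x$cp_kcal_mol_C <- -x$cp_kcal_mol_C
  }
  x
}

#' Read a Raman spectrum
#'
#' CSV columns `wavenumber_cm1`, `intensity_au` (or `intensity`); sidecar
#' fields `membrane`, `molar_ratio`, `accumulations` become attributes.
#'
#' @param path CSV path.
#' @return A spectrum tibble (`wavenumber_cm1`, `intensity`).
#' @export
read_raman_spectrum <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("intensity_au" %in% names(x) && !"intensity" %in% names(x)) {
    x$intensity <- x$intensity_au
    x$intensity_au <- NULL
  }
  x <- as_spectrum(x)
  apply_meta(x, read_sidecar(path), c(membrane = "membrane",
                                      molar_ratio = "molar_ratio",
                                      accumulations = "accumulations"))
}

#' Read a tensiometry record table
#'
#' CSV columns `membrane`, `serotonin_mM`, `gamma_m_mN_m`, `theta_deg`
#' (optional SD columns pass through), ready for [tension_table()].
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_tension_records <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("membrane", "serotonin_mM", "gamma_m_mN_m", "theta_deg")
  if (!all(need %in% names(x))) {
    abort(sprintf("Tensiometry CSV must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  x
}

#' Write a tibble plus JSON metadata sidecar
#'
#' @param x Data frame to write.
#' @param path CSV destination; metadata (if any) goes to the matching
#'   `.json` file.
#' @param meta Named list of metadata fields.
#' @return `path`, invisibly.
#' @export
write_with_sidecar <- function(x, path, meta = list()) {
  readr::write_csv(x, path)
  if (length(meta)) {
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a complete synthetic study directory
#'
#' Emits the raw instrument records of the full factorial design (droplet
#' traces, thermograms, Raman spectra + reference, a tensiometry table) as
#' CSVs with JSON sidecars, one file per condition/replicate, mirroring the
#' layout [run_full_pipeline()] consumes.
#'
#' @inheritParams gen_study_dataset
#' @param dir Output directory (created if missing).
#' @param n_replicates Replicates per condition.
#' @param radius_noise_cv Frame-level radius noise of the droplet traces;
#'   see [run_full_pipeline()].
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(dir, em = default_effect_model(),
                                  n_replicates = 3, seed = 1,
                                  radius_noise_cv = 0.001) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("dib", "dsc", "raman")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  safe <- function(m) gsub("[^A-Za-z0-9]+", "-", m)
  i <- 0L
  for (m in MEMBRANES) {
    for (conc in CONC_LEVELS_MM) {
      for (rep in seq_len(n_replicates)) {
        i <- i + 1L
        tag <- sprintf("%s_c%02d_r%d", safe(m), conc, rep)
        ts <- gen_droplet_timeseries(em, m, conc, seed = seed + 7L * i,
                                     radius_noise_cv = radius_noise_cv)
        write_with_sidecar(
          tibble::as_tibble(ts), file.path(dir, "dib", paste0(tag, ".csv")),
          meta = list(membrane = m, conc_mM = conc,
                      osmolality_mOsm_kg = attr(ts, "osmolality_hyper"),
                      theta_deg = attr(ts, "theta_deg"),
                      temperature_C = attr(ts, "temperature_C"),
                      pf_true = attr(ts, "pf_true")))
        tg <- gen_thermogram(em, m, conc, seed = seed + 7L * i + 1L)
        write_with_sidecar(
          tibble::as_tibble(tg), file.path(dir, "dsc", paste0(tag, ".csv")),
          meta = list(membrane = m, conc_mM = conc, direction = "heating",
                      scan_rate_C_min = 5, tm_true = attr(tg, "tm_true"),
                      dh_true = attr(tg, "dh_true")))
        sp <- gen_raman_spectrum(em, m, conc, seed = seed + 7L * i + 2L)
        write_with_sidecar(
          sp$spectrum, file.path(dir, "raman", paste0(tag, ".csv")),
          meta = list(membrane = m, conc_mM = conc,
                      ratio_true = attr(sp$spectrum, "ratio_true")))
        if (i == 1L) {
          write_with_sidecar(sp$reference,
                             file.path(dir, "raman", "reference.csv"),
                             meta = list(sample = "guest reference"))
        }
      }
    }
  }
  withr_seed(seed + 999983L, {
    tens <- purrr::map_dfr(MEMBRANES, function(m) {
      g0 <- effect_level(em, m, "gamma_m", CONC_LEVELS_MM)
      th0 <- effect_level(em, m, "theta", CONC_LEVELS_MM)
      tibble::tibble(
        membrane = m, serotonin_mM = CONC_LEVELS_MM,
        gamma_m_mN_m = g0 * (1 + c(0, rnorm(length(g0) - 1, 0, 0.002))),
        theta_deg = th0 + c(0, rnorm(length(th0) - 1, 0, 0.05))
      )
    })
    readr::write_csv(tens, file.path(dir, "tensiometry.csv"))
  })
  invisible(dir)
}
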