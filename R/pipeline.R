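# End-to-end analysis: raw (or synthetic) instrument records -> per-assay
# result tables -> control-normalised tables -> ANOVA/Tukey annotations.

#' Run the full factorial analysis pipeline
#'
#' Reproduces the study-level analysis chain on a directory of instrument
#' records (layout of [write_synthetic_study()]) or on synthetic data
#' generated in memory. Per-assay chains: droplet traces ->
#' [estimate_pf()]; thermograms -> [baseline_correct()] +
#' [analyze_transition()]; Raman spectra -> [preprocess_spectrum()] +
#' [subtract_reference()] + [ch_stretch_ratios()]; tensiometry records ->
#' [tension_table()]. Cell values are then normalised to their membrane
#' controls and analysed by two-way ANOVA with Tukey HSD annotations.
#' Deterministic given `seed`; every output table is regenerable from the
#' configuration and inputs alone.
#'
#' @param input_dir Directory of instrument CSVs; `NULL` (default) runs on
#'   synthetic data.
#' @param em Effect model for synthetic generation.
#' @param n_replicates Synthetic replicates per cell; single number or named
#'   per-observable vector (e.g. `c(pf = 10, tm = 3)`).
#' @param seed Integer seed for all synthetic draws.
#' @param pf_method Permeability estimator, `"ode_fit"` or
#'   `"initial_rate"`.
#' @param radius_noise_cv Frame-level multiplicative radius noise of the
#'   synthetic droplet traces. The default 0.001 makes the per-run
#'   permeability spread (frame noise through the estimator, ~2.4%, plus 3%
#'   run-to-run variation) match the replicate SDs reported for this kind
#'   of assay; larger values stress-test the estimator instead.
#' @param out_dir If non-`NULL`, result tables are written there as CSVs
#'   together with `run_log.json` (seed, configuration echo, package
#'   version).
#' @return A list of tibbles: `measurements` (tidy per-replicate values for
#'   `pf`, `tm`, `dh`, `fwhm`, `ratio`), `normalized` (with `rel_value`),
#'   `tension` (per-condition bilayer tension with `rel_gamma_b`), `anova`
#'   (per-observable ANOVA tables), `tukey` (per-observable pairwise
#'   comparisons), and `log` (the run configuration).
#' @examples
#' \donttest{
#' res <- run_full_pipeline(n_replicates = 2, seed = 7)
#' res$normalized
#' }
#' @export
run_full_pipeline <- function(input_dir = NULL, em = default_effect_model(),
                              n_replicates = 3, seed = 1,
                              pf_method = c("ode_fit", "initial_rate"),
                              radius_noise_cv = 0.001, out_dir = NULL) {
  pf_method <- match.arg(pf_method)
  if (is.null(input_dir)) {
    raw <- synth_raw_records(em, n_replicates, seed, radius_noise_cv)
  } else {
    raw <- load_raw_records(input_dir)
  }
  pf_tbl <- purrr::map_dfr(raw$dib, function(rec) {
    fit <- estimate_pf(rec$data, method = pf_method)
    tibble::tibble(membrane = rec$membrane, conc = rec$conc,
                   replicate = rec$replicate, observable = "pf",
                   value = fit$pf_um_s)
  })
  dsc_tbl <- purrr::map_dfr(raw$dsc, function(rec) {
    tr <- analyze_transition(baseline_correct(rec$data))
    tibble::tibble(membrane = rec$membrane, conc = rec$conc,
                   replicate = rec$replicate,
                   observable = c("tm", "dh", "fwhm"),
                   value = c(tr$Tm_C, tr$dH_kcal_mol, tr$fwhm_C))
  })
  ref <- preprocess_reference(raw$raman_reference)
  raman_tbl <- purrr::map_dfr(raw$raman, function(rec) {
    s <- preprocess_spectrum(rec$data)
    if (rec$conc > 0 && !is.null(ref)) s <- subtract_reference(s, ref)
    tibble::tibble(membrane = rec$membrane, conc = rec$conc,
                   replicate = rec$replicate, observable = "ratio",
                   value = ch_stretch_ratios(s)$r_2930_2890)
  })
  measurements <- dplyr::bind_rows(pf_tbl, dsc_tbl, raman_tbl)
  normalized <- measurements |>
    dplyr::group_by(.data$observable) |>
    dplyr::group_modify(~ normalize_to_control(.x)) |>
    dplyr::ungroup()
  tension <- tension_table(raw$tension)
  per_obs <- split(measurements, measurements$observable)
  anova_tbl <- purrr::map_dfr(names(per_obs), function(obs) {
    dplyr::mutate(tidy(two_way_anova(per_obs[[obs]])), observable = obs,
                  .before = 1)
  })
  tukey_tbl <- purrr::map_dfr(names(per_obs), function(obs) {
    dplyr::mutate(tukey_hsd(per_obs[[obs]]), observable = obs, .before = 1)
  })
  log <- list(seed = seed, input_dir = input_dir %||% "synthetic",
              n_replicates = n_replicates, pf_method = pf_method,
              package_version = as.character(utils::packageVersion("memphys")))
  res <- list(measurements = measurements, normalized = normalized,
              tension = tension, anova = anova_tbl, tukey = tukey_tbl,
              log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("measurements", "normalized", "tension", "anova", "tukey")) {
      readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Baseline-correct a guest-molecule reference spectrum
#'
#' Like [preprocess_spectrum()] but for the pure guest (serotonin-like)
#' reference, which has no 2850 cm^-1 lipid band to normalise to: the
#' polynomial baseline is fitted outside the indole and C-H windows,
#' subtracted, and negative residuals clipped; no rescaling is applied
#' (the 1540 cm^-1 anchor in [subtract_reference()] sets the scale).
#'
#' @param ref Raw reference spectrum tibble.
#' @return The baseline-corrected reference spectrum.
#' @export
preprocess_reference <- function(ref) {
  if (is.null(ref)) return(NULL)
  s <- as_spectrum(ref)
  wins <- RAMAN_WINDOWS[c("indole_1540", "band_2930")]
  pad <- 50
  in_peak <- Reduce(`|`, lapply(wins, function(w) {
    s$wavenumber_cm1 >= w[1] - pad & s$wavenumber_cm1 <= w[2] + pad
  }))
  xm <- scale(s$wavenumber_cm1)[, 1]
  fit <- lm(s$intensity[!in_peak] ~ poly(xm[!in_peak], 3, raw = TRUE))
  baseline <- cbind(1, poly(xm, 3, raw = TRUE)) %*% coef(fit)
  tibble::tibble(wavenumber_cm1 = s$wavenumber_cm1,
                 intensity = pmax(s$intensity - as.numeric(baseline), 0))
}

# replicate sensitivity summary used in end-to-end checks and reports:
# relative change of each observable at the top concentration
#' Per-membrane sensitivity summary
#'
#' Summarises a pipeline run as the relative change of each observable's
#' cell mean at the highest concentration versus its control — the scalar
#' each membrane's responsiveness is ranked by.
#'
#' @param normalized The `normalized` table of [run_full_pipeline()].
#' @return A tibble: `observable`, `membrane`, `sensitivity` (relative
#'   change at the top concentration; sign follows the effect direction).
#' @export
membrane_sensitivity <- function(normalized) {
  normalized |>
    dplyr::filter(.data$conc == max(.data$conc)) |>
    dplyr::group_by(.data$observable, .data$membrane) |>
    dplyr::summarise(sensitivity = mean(.data$rel_value) - 1,
                     .groups = "drop")
}

synth_raw_records <- function(em, n_replicates, seed, radius_noise_cv = 0.001) {
  reps_for <- function(obs) {
    if (length(n_replicates) == 1 && is.null(names(n_replicates))) {
      as.integer(n_replicates)
    } else {
      as.integer(n_replicates[[obs]] %||% 3L)
    }
  }
  grid <- tidyr::expand_grid(membrane = MEMBRANES, conc = CONC_LEVELS_MM)
  i <- 0L
  dib <- list(); dsc <- list(); raman <- list()
  for (r in seq_len(nrow(grid))) {
    m <- grid$membrane[r]; conc <- grid$conc[r]
    for (rep in seq_len(reps_for("pf"))) {
      i <- i + 1L
      # run-to-run biological variation on top of frame-level radius noise
      mu <- effect_level(em, m, "pf", conc)
      pf_run <- withr_seed(seed + 13L * i, {
        rnorm(1, mu, effect_noise_sd(em, m, "pf", mu))
      })
      dib[[length(dib) + 1L]] <- list(
        membrane = m, conc = conc, replicate = rep,
        data = gen_droplet_timeseries(em, m, conc, seed = seed + 13L * i + 1L,
                                      radius_noise_cv = radius_noise_cv,
                                      pf_um_s = max(pf_run, 1)))
    }
    for (rep in seq_len(reps_for("tm"))) {
      i <- i + 1L
      pars <- withr_seed(seed + 13L * i, {
        tm_mu <- effect_level(em, m, "tm", conc)
        dh_mu <- effect_level(em, m, "dh", conc)
        fw_mu <- effect_level(em, m, "fwhm", conc)
        c(rnorm(1, tm_mu, effect_noise_sd(em, m, "tm", tm_mu)),
          rnorm(1, dh_mu, effect_noise_sd(em, m, "dh", dh_mu)),
          rnorm(1, fw_mu, effect_noise_sd(em, m, "fwhm", fw_mu)))
      })
      dsc[[length(dsc) + 1L]] <- list(
        membrane = m, conc = conc, replicate = rep,
        data = gen_thermogram(em, m, conc, seed = seed + 13L * i + 1L,
                              tm = pars[1], dh = max(pars[2], 0.05),
                              fwhm = max(pars[3], 0.2)))
    }
    for (rep in seq_len(reps_for("ratio"))) {
      i <- i + 1L
      sp <- gen_raman_spectrum(em, m, conc, seed = seed + 13L * i)
      raman[[length(raman) + 1L]] <- list(
        membrane = m, conc = conc, replicate = rep, data = sp$spectrum)
    }
  }
  reference <- gen_raman_spectrum(em, MEMBRANES[1], 0,
                                  seed = seed + 424243L)$reference
  tension <- purrr::map_dfr(MEMBRANES, function(m) {
    tibble::tibble(
      membrane = m, serotonin_mM = CONC_LEVELS_MM,
      gamma_m_mN_m = effect_level(em, m, "gamma_m", CONC_LEVELS_MM),
      theta_deg = effect_level(em, m, "theta", CONC_LEVELS_MM))
  })
  list(dib = dib, dsc = dsc, raman = raman, raman_reference = reference,
       tension = tension)
}

load_raw_records <- function(input_dir) {
  need_dirs <- file.path(input_dir, c("dib", "dsc", "raman"))
  if (!all(dir.exists(need_dirs)) ||
      !file.exists(file.path(input_dir, "tensiometry.csv"))) {
    abort(sprintf(
      "`%s` must contain dib/, dsc/, raman/ and tensiometry.csv.", input_dir))
  }
  read_group <- function(sub, reader) {
    files <- sort(list.files(file.path(input_dir, sub), pattern = "\\.csv$",
                             full.names = TRUE))
    files <- files[basename(files) != "reference.csv"]
    purrr::imap(files, function(f, idx) {
      meta <- read_sidecar(f)
      if (is.null(meta$membrane) || is.null(meta$conc_mM)) {
        abort(sprintf("%s: sidecar must provide `membrane` and `conc_mM`.", f))
      }
      list(membrane = meta$membrane, conc = meta$conc_mM,
           replicate = idx, data = reader(f))
    })
  }
  ref_path <- file.path(input_dir, "raman", "reference.csv")
  list(
    dib = read_group("dib", read_droplet_timeseries),
    dsc = read_group("dsc", read_thermogram),
    raman = read_group("raman", read_raman_spectrum),
    raman_reference = if (file.exists(ref_path)) read_raman_spectrum(ref_path),
    tension = read_tension_records(file.path(input_dir, "tensiometry.csv"))
  )
}
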