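# Raman C-H stretching band-ratio analysis.
#
# A spectrum is a tibble with columns `wavenumber_cm1` (increasing) and
# `intensity` (arbitrary units). The C-H stretching region (2800-3000 cm^-1)
# carries three bands: ~2850 (methylene symmetric), ~2890 (methylene
# antisymmetric) and ~2930 cm^-1 (terminal methyl symmetric); their
# intensity ratios report acyl-chain conformational order and lateral
# packing. A guest molecule with an indole ring contributes its own bands,
# anchored here at ~1540 cm^-1 (indole ring stretch), which is used to scale
# the reference spectrum for subtraction.

# analysis windows, cm^-1
RAMAN_WINDOWS <- list(
  band_2850 = c(2840, 2860),
  band_2890 = c(2880, 2900),
  band_2930 = c(2920, 2940),
  indole_1540 = c(1520, 1560)
)

as_spectrum <- function(s) {
  stopifnot(is.data.frame(s), all(c("wavenumber_cm1", "intensity") %in% names(s)))
  if (is.unsorted(s$wavenumber_cm1, strictly = TRUE)) {
    abort("Wavenumber grid must be strictly increasing.")
  }
  tibble::as_tibble(s)
}

window_max <- function(s, win) {
  sel <- s$wavenumber_cm1 >= win[1] & s$wavenumber_cm1 <= win[2]
  if (!any(sel)) {
    abort(sprintf("Spectrum grid does not cover the %g-%g cm^-1 window.",
                  win[1], win[2]), class = "memphys_bad_window")
  }
  max(s$intensity[sel])
}

#' Baseline-correct and normalise a Raman spectrum
#'
#' Fits a polynomial baseline (default cubic) to the non-peak regions of the
#' grid — everything outside the C-H band windows, the 1520–1560 cm^-1
#' indole window and any extra windows supplied — subtracts it, and rescales
#' the trace so the 2850 cm^-1 band maximum equals 1.
#'
#' @param s Spectrum tibble (`wavenumber_cm1`, `intensity`).
#' @param poly_degree Baseline polynomial degree.
#' @param exclude Extra peak windows (list of length-2 vectors) excluded
#'   from the baseline fit, besides the built-in band windows.
#' @return The corrected, unit-2850 normalised spectrum.
#' @examples
#' s <- gen_raman_spectrum(conc = 0, seed = 1)$spectrum
#' preprocess_spectrum(s)
#' @export
preprocess_spectrum <- function(s, poly_degree = 3, exclude = list()) {
  s <- as_spectrum(s)
  wins <- c(RAMAN_WINDOWS, exclude)
  # widen band windows for baseline-fit exclusion so band tails do not pull
  # the polynomial
  pad <- 50
  in_peak <- Reduce(`|`, lapply(wins, function(w) {
    s$wavenumber_cm1 >= w[1] - pad & s$wavenumber_cm1 <= w[2] + pad
  }))
  if (sum(!in_peak) <= poly_degree + 1) {
    abort("Not enough baseline (non-peak) points for the polynomial fit.",
          class = "memphys_bad_window")
  }
  x <- s$wavenumber_cm1
  xm <- scale(x)[, 1] # condition the polynomial basis
  fit <- lm(s$intensity[!in_peak] ~ poly(xm[!in_peak], poly_degree, raw = TRUE))
  baseline <- cbind(1, poly(xm, poly_degree, raw = TRUE)) %*% coef(fit)
  corrected <- s$intensity - as.numeric(baseline)
  out <- tibble::tibble(wavenumber_cm1 = x, intensity = corrected)
  peak <- window_max(out, RAMAN_WINDOWS$band_2850)
  resid_sd <- sd(corrected[!in_peak])
  if (peak <= 0 || (is.finite(resid_sd) && peak < 5 * max(resid_sd, 1e-12))) {
    abort("No discernible 2850 cm^-1 band: unusable spectrum.",
          class = "memphys_no_band")
  }
  out$intensity <- out$intensity / peak
  out
}

#' Subtract a scaled guest-molecule reference spectrum
#'
#' Scales the reference by the ratio of the sample to reference intensities
#' of the 1540 cm^-1 indole band (windowed maxima over 1520–1560 cm^-1),
#' subtracts it, clips negative residuals at zero, and re-normalises the
#' result to the 2850 cm^-1 band. Both spectra should already be
#' preprocessed ([preprocess_spectrum()]).
#'
#' @param s Preprocessed sample spectrum.
#' @param ref Preprocessed reference (pure guest molecule) spectrum; must
#'   carry a 1540 cm^-1 band.
#' @param renormalize Re-normalise the difference to unit 2850 intensity
#'   (default `TRUE`; disable to inspect raw residuals).
#' @return The lipid-only spectrum estimate, with the scale factor `k` and
#'   the summed negative residual (a QC metric, before clipping) attached
#'   as attributes `k` and `negative_residual`.
#' @export
subtract_reference <- function(s, ref, renormalize = TRUE) {
  s <- as_spectrum(s)
  ref <- as_spectrum(ref)
  ref_1540 <- window_max(ref, RAMAN_WINDOWS$indole_1540)
  if (ref_1540 <= 1e-9) {
    abort("Reference spectrum lacks a 1540 cm^-1 indole band.",
          class = "memphys_no_band")
  }
  k <- window_max(s, RAMAN_WINDOWS$indole_1540) / ref_1540
  k <- max(k, 0)
  ref_on_s <- approx(ref$wavenumber_cm1, ref$intensity,
                     xout = s$wavenumber_cm1, rule = 2)$y
  diffv <- s$intensity - k * ref_on_s
  neg <- sum(pmin(diffv, 0))
  out <- tibble::tibble(wavenumber_cm1 = s$wavenumber_cm1,
                        intensity = pmax(diffv, 0))
  if (renormalize) {
    peak <- window_max(out, RAMAN_WINDOWS$band_2850)
    if (peak > 0) out$intensity <- out$intensity / peak
  }
  attr(out, "k") <- k
  attr(out, "negative_residual") <- neg
  out
}

#' C-H stretching band intensities and order ratios
#'
#' Band intensities are windowed maxima (2840–2860, 2880–2900, 2920–2940
#' cm^-1). The key order parameter is the terminal-methyl to antisymmetric-
#' methylene ratio \eqn{I_{2930}/I_{2890}}; higher values mean more gauche
#' content and looser chain packing. When `control_ratio` is supplied the
#' relative ratio \eqn{I/I_\circ} is reported against it.
#'
#' @param s Preprocessed (and, if needed, reference-subtracted) spectrum.
#' @param control_ratio Optional control value of `r_2930_2890` for the
#'   relative ratio.
#' @return A one-row tibble: `I2850`, `I2890`, `I2930`, `r_2930_2890`,
#'   `r_2930_2850`, `rel_ratio` (NA without a control).
#' @examples
#' s <- preprocess_spectrum(gen_raman_spectrum(conc = 0, seed = 1)$spectrum)
#' ch_stretch_ratios(s)
#' @export
ch_stretch_ratios <- function(s, control_ratio = NULL) {
  s <- as_spectrum(s)
  i2850 <- window_max(s, RAMAN_WINDOWS$band_2850)
  i2890 <- window_max(s, RAMAN_WINDOWS$band_2890)
  i2930 <- window_max(s, RAMAN_WINDOWS$band_2930)
  r1 <- i2930 / i2890
  r2 <- i2930 / i2850
  tibble::tibble(
    I2850 = i2850, I2890 = i2890, I2930 = i2930,
    r_2930_2890 = r1, r_2930_2850 = r2,
    rel_ratio = if (is.null(control_ratio)) NA_real_ else r1 / control_ratio
  )
}
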