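# DSC thermogram reduction.
#
# A thermogram is a tibble with columns `T_C` (increasing temperature grid,
# degC; the grid need not be uniform) and `cp_kcal_mol_C` (molar excess heat
# capacity, kcal mol^-1 degC^-1). All integrals are trapezoidal.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Baseline lines under the two flanks, which may carry the transition
# peak's tail. Fits, jointly over both flanks,
#   y ~ (a_L + b_L x) 1_left + (a_R + b_R x) 1_right + c / (x - x_peak)^2
# with the shared inverse-square term standing in for a heavy
# (Lorentzian-like) peak tail, and returns the two (a, b) lines only.
# A positive tail amplitude is physical; keeping it (even when noisy)
# leaves the lines unbiased, whereas dropping it folds the tail into the
# baseline systematically. A negative fitted amplitude is unphysical, so
# the model degenerates to two plain lines (clean Gaussian-tailed flanks).
flank_baseline_lines <- function(x_lo, y_lo, x_hi, y_hi, x_peak) {
  plain <- function() {
    list(lo = as.numeric(coef(lm(y_lo ~ x_lo))),
         hi = as.numeric(coef(lm(y_hi ~ x_hi))))
  }
  is_lo <- c(rep(1, length(x_lo)), rep(0, length(x_hi)))
  x <- c(x_lo, x_hi)
  y <- c(y_lo, y_hi)
  X <- cbind(lo_i = is_lo, lo_x = is_lo * x,
             hi_i = 1 - is_lo, hi_x = (1 - is_lo) * x,
             z = 1 / (x - x_peak)^2)
  cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(cf) || !all(is.finite(cf)) || cf[["z"]] <= 0) return(plain())
  list(lo = as.numeric(cf[1:2]), hi = as.numeric(cf[3:4]))
}

as_thermogram <- function(df) {
  stopifnot(is.data.frame(df), all(c("T_C", "cp_kcal_mol_C") %in% names(df)))
  if (is.unsorted(df$T_C, strictly = TRUE)) {
    abort("Thermogram temperature grid must be strictly increasing.")
  }
  tibble::as_tibble(df)
}

#' Subtract the instrumental baseline from a DSC thermogram
#'
#' Fits straight lines to the pre- and post-transition flanks and
#' interpolates between them under the peak. Flanks start as the outer
#' `flank_frac` of the scan window and are widened to everything beyond
#' three rough peak widths from the apex when that gives more points. The
#' two lines are fitted jointly with a shared inverse-square peak-tail term
#' (see the model comment in the source) so heavy transition tails do not
#' tilt the baseline. The default interpolation between the lines is
#' sigmoidal, weighted by the cumulative peak area, which places the
#' baseline step where the transition actually occurs; `method = "linear"`
#' joins them with a single straight interpolation instead. The
#' fit/subtract cycle is iterated so the area weighting comes from a
#' corrected trace.
#'
#' @param tg Thermogram tibble (`T_C`, `cp_kcal_mol_C`); heating scans carry
#'   a positive (endothermic) peak. For cooling scans flip the sign first.
#' @param flank_frac Fraction of the window treated as flank on each side.
#' @param method `"sigmoid"` (default) or `"linear"`.
#' @param n_iter Fit/subtract iterations for the sigmoid weighting.
#' @return The thermogram with the baseline removed; the fitted baseline is
#'   attached as attribute `baseline`.
#' @examples
#' tg <- gen_thermogram(tm = -16.68, dh = 8.34, fwhm = 1.5, noise_sd = 0)
#' bc <- baseline_correct(tg)
#' @export
baseline_correct <- function(tg, flank_frac = 0.15,
                             method = c("sigmoid", "linear"), n_iter = 4) {
  method <- match.arg(method)
  tg <- as_thermogram(tg)
  T_C <- tg$T_C
  cp <- tg$cp_kcal_mol_C
  n <- length(T_C)
  span <- diff(range(T_C))
  lo <- T_C <= T_C[1] + flank_frac * span
  hi <- T_C >= T_C[n] - flank_frac * span
  if (sum(lo) < 3 || sum(hi) < 3) {
    abort("Flank windows too small to fit a baseline.", class = "memphys_bad_window")
  }
  # locate the peak against a chord through the window ends (a fit through
  # the whole flanks would flatten a peak that strays into one)
  end_l <- mean(cp[1:min(5, n)])
  end_r <- mean(cp[max(1, n - 4):n])
  chord <- end_l + (end_r - end_l) * (T_C - T_C[1]) / (T_C[n] - T_C[1])
  detr <- cp - chord
  ipk <- which.max(detr)
  if (!is.finite(detr[ipk]) || detr[ipk] <= 0) {
    # no excess signal above the flank interpolation: subtract a plain
    # linearly interpolated two-line baseline
    c_lo <- coef(lm(cp[lo] ~ T_C[lo]))
    c_hi <- coef(lm(cp[hi] ~ T_C[hi]))
    w <- (T_C - T_C[1]) / (T_C[n] - T_C[1])
    baseline <- (1 - w) * (c_lo[[1]] + c_lo[[2]] * T_C) +
      w * (c_hi[[1]] + c_hi[[2]] * T_C)
    out <- tibble::tibble(T_C = T_C, cp_kcal_mol_C = cp - baseline)
    attr(out, "baseline") <- baseline
    return(out)
  }
  if (lo[ipk] || hi[ipk]) {
    abort("Transition peak lies inside a baseline flank: unsuitable scan window.",
          class = "memphys_bad_window")
  }
  # widen the flanks up to +/- 3 rough peak widths from the peak: the extra
  # lever arm keeps the interpolated baseline stable under noise
  fwhm_rough <- max(sum(detr >= detr[ipk] / 2) * median(diff(T_C)),
                    2 * median(diff(T_C)))
  lo_w <- T_C <= T_C[ipk] - 3 * fwhm_rough
  hi_w <- T_C >= T_C[ipk] + 3 * fwhm_rough
  if (sum(lo_w) > sum(lo)) lo <- lo_w
  if (sum(hi_w) > sum(hi)) hi <- hi_w
  lines <- flank_baseline_lines(T_C[lo], cp[lo], T_C[hi], cp[hi], T_C[ipk])
  b_lo <- lines$lo[1] + lines$lo[2] * T_C
  b_hi <- lines$hi[1] + lines$hi[2] * T_C
  if (method == "linear") {
    w <- (T_C - T_C[1]) / (T_C[n] - T_C[1])
    baseline <- (1 - w) * b_lo + w * b_hi
  } else {
    baseline <- (b_lo + b_hi) / 2
    for (i in seq_len(n_iter)) {
      resid <- pmax(cp - baseline, 0)
      cum <- c(0, cumsum(diff(T_C) * (head(resid, -1) + tail(resid, -1)) / 2))
      total <- cum[n]
      w <- if (total > 0) cum / total else (T_C - T_C[1]) / (T_C[n] - T_C[1])
      baseline <- (1 - w) * b_lo + w * b_hi
    }
  }
  out <- tibble::tibble(T_C = T_C, cp_kcal_mol_C = cp - baseline)
  attr(out, "baseline") <- baseline
  out
}

#' Reduce a baseline-corrected thermogram to its transition parameters
#'
#' Locates the dominant endothermic peak and reports the main transition
#' temperature `Tm_C` (argmax with parabolic three-point refinement), the
#' calorimetric enthalpy `dH_kcal_mol` (trapezoidal integral over the peak
#' support: the region where the corrected trace exceeds
#' `support_frac` of the peak height, extended outward to the nearest
#' zero crossings) and the full width at half maximum `fwhm_C` (linear
#' interpolation of the half-height crossings).
#'
#' @param tg Baseline-corrected thermogram (see [baseline_correct()]).
#' @param noise_k Peak detection threshold in units of the flank SD: a peak
#'   lower than `noise_k` times the SD of the outer 15% of the trace is
#'   reported as "no transition detected".
#' @param support_frac Fraction of peak height defining the integration
#'   support before zero-crossing extension.
#' @return A one-row tibble: `Tm_C`, `dH_kcal_mol`, `fwhm_C`, `peak_height`.
#' @examples
#' tg <- gen_thermogram(tm = -16.68, dh = 8.34, fwhm = 1.5, noise_sd = 0)
#' analyze_transition(baseline_correct(tg))
#' @export
analyze_transition <- function(tg, noise_k = 5, support_frac = 0.01) {
  tg <- as_thermogram(tg)
  T_C <- tg$T_C
  cp <- tg$cp_kcal_mol_C
  n <- length(T_C)
  flank <- T_C <= T_C[1] + 0.15 * diff(range(T_C)) |
    T_C >= T_C[n] - 0.15 * diff(range(T_C))
  noise_sd <- sd(cp[flank])
  ipk <- which.max(cp)
  height <- cp[ipk]
  if (!is.finite(height) || height <= 0 ||
      (is.finite(noise_sd) && noise_sd > 0 && height < noise_k * noise_sd)) {
    abort("No transition detected above the noise floor.",
          class = "memphys_no_transition")
  }
  if (ipk <= 1 || ipk >= n) {
    abort("Transition peak sits at the window edge.", class = "memphys_bad_window")
  }
  # apex by quadratic fit over the contiguous peak top (robust to
  # point-level noise; exact for a symmetric peak, grid may be non-uniform)
  top_l <- ipk
  while (top_l > 1 && cp[top_l - 1] >= 0.75 * height) top_l <- top_l - 1
  top_r <- ipk
  while (top_r < n && cp[top_r + 1] >= 0.75 * height) top_r <- top_r + 1
  tm <- if (top_r - top_l + 1 >= 5) {
    ii <- top_l:top_r
    q <- coef(lm(cp[ii] ~ poly(T_C[ii] - T_C[ipk], 2, raw = TRUE)))
    if (is.finite(q[[3]]) && q[[3]] < 0) {
      T_C[ipk] - q[[2]] / (2 * q[[3]])
    } else {
      T_C[ipk]
    }
  } else {
    y0 <- cp[ipk - 1]; y1 <- cp[ipk]; y2 <- cp[ipk + 1]
    q <- coef(lm(c(y0, y1, y2) ~ poly(T_C[(ipk - 1):(ipk + 1)] - T_C[ipk],
                                      2, raw = TRUE)))
    if (is.finite(q[[3]]) && q[[3]] < 0) T_C[ipk] - q[[2]] / (2 * q[[3]])
    else T_C[ipk]
  }
  # integration support decided on a lightly smoothed trace so point-level
  # noise does not stop the zero-crossing extension early; the raw trace is
  # what gets integrated
  fwhm_rough <- sum(cp >= height / 2) * median(diff(T_C))
  k <- max(1L, as.integer(round(fwhm_rough / (3 * median(diff(T_C))))))
  if (k %% 2L == 0L) k <- k + 1L
  cps <- if (k > 1) {
    as.numeric(stats::filter(cp, rep(1 / k, k), sides = 2))
  } else {
    cp
  }
  cps[is.na(cps)] <- cp[is.na(cps)]
  above <- cps >= support_frac * height
  l <- ipk
  while (l > 1 && above[l - 1]) l <- l - 1
  r <- ipk
  while (r < n && above[r + 1]) r <- r + 1
  while (l > 1 && cps[l - 1] > 0) l <- l - 1
  while (r < n && cps[r + 1] > 0) r <- r + 1
  dh <- trapz(T_C[l:r], cp[l:r])
  # fwhm by linear interpolation of the half-height crossings
  half <- height / 2
  li <- ipk
  while (li > l && cp[li - 1] > half) li <- li - 1
  ri <- ipk
  while (ri < r && cp[ri + 1] > half) ri <- ri + 1
  t_left <- if (li == 1) T_C[1] else
    approx(cp[(li - 1):li], T_C[(li - 1):li], xout = half)$y
  t_right <- if (ri == n) T_C[n] else
    approx(cp[ri:(ri + 1)], T_C[ri:(ri + 1)], xout = half)$y
  tibble::tibble(Tm_C = tm, dH_kcal_mol = dh,
                 fwhm_C = t_right - t_left, peak_height = height)
}

#' Control-relative thermodynamic summary
#'
#' Adds the transition-temperature shift \eqn{\Delta T_m = T_m - T_m^\circ}
#' and the relative enthalpy \eqn{\Delta H / \Delta H^\circ} to a table of
#' per-condition transition parameters, using each membrane's
#' zero-concentration row as the control.
#'
#' @param summaries A data frame with columns `membrane`, `conc` (0 = the
#'   control), `Tm_C`, `dH_kcal_mol`; extra columns pass through.
#' @return The input with `dTm_C` and `rel_dH` added.
#' @examples
#' thermo_summary(data.frame(membrane = "DOPC", conc = c(0, 25),
#'                           Tm_C = c(-16.68, -17.78),
#'                           dH_kcal_mol = c(8.34, 5.31)))
#' @export
thermo_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("membrane", "conc", "Tm_C", "dH_kcal_mol") %in% names(summaries)))
  ctrl <- summaries |>
    dplyr::group_by(.data$membrane) |>
    dplyr::summarise(n0 = sum(.data$conc == 0), .groups = "drop")
  if (any(ctrl$n0 != 1)) {
    abort("Each membrane needs exactly one control (conc == 0) row.",
          class = "memphys_missing_control")
  }
  summaries |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$membrane) |>
    dplyr::mutate(
      dTm_C = .data$Tm_C - .data$Tm_C[.data$conc == 0],
      rel_dH = .data$dH_kcal_mol / .data$dH_kcal_mol[.data$conc == 0]
    ) |>
    dplyr::ungroup()
}
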