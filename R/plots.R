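# ggplot2 QC plots for the main result types.

#' Plot a droplet shrink/swell trace
#'
#' @param ts A `droplet_timeseries` tibble.
#' @return A ggplot: both droplet diameters against time.
#' @export
plot_droplet_timeseries <- function(ts) {
  long <- tidyr::pivot_longer(tibble::as_tibble(ts),
                              c("d1_um", "d2_um"),
                              names_to = "droplet", values_to = "d_um")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$d_um,
                                     colour = .data$droplet)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "droplet diameter (µm)",
                  colour = NULL) +
    ggplot2::scale_colour_discrete(labels = c(d1_um = "solute (swelling)",
                                              d2_um = "partner (shrinking)"))
}

#' Plot a thermogram with its fitted baseline
#'
#' @param tg Raw thermogram tibble.
#' @param corrected Optionally the output of [baseline_correct()] on `tg`
#'   (computed if missing); its `baseline` attribute is overlaid.
#' @return A ggplot of the trace, baseline and corrected trace.
#' @export
plot_thermogram <- function(tg, corrected = NULL) {
  corrected <- corrected %||% baseline_correct(tg)
  df <- dplyr::bind_rows(
    tibble::tibble(T_C = tg$T_C, cp = tg$cp_kcal_mol_C, trace = "raw"),
    tibble::tibble(T_C = tg$T_C, cp = attr(corrected, "baseline"),
                   trace = "baseline"),
    tibble::tibble(T_C = corrected$T_C, cp = corrected$cp_kcal_mol_C,
                   trace = "corrected")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$T_C, .data$cp,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = "excess heat capacity (kcal mol⁻¹ °C⁻¹)",
                  colour = NULL)
}

#' Plot a Raman spectrum with the C-H band windows
#'
#' @param s Spectrum tibble.
#' @param zoom If `TRUE` (default), restrict to the 2800-3000 cm^-1 C-H
#'   stretching region.
#' @return A ggplot of the spectrum with shaded analysis windows.
#' @export
plot_spectrum <- function(s, zoom = TRUE) {
  s <- as_spectrum(s)
  wins <- purrr::imap_dfr(RAMAN_WINDOWS[1:3], function(w, nm) {
    tibble::tibble(xmin = w[1], xmax = w[2], band = nm)
  })
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$wavenumber_cm1, .data$intensity)) +
    ggplot2::geom_rect(data = wins,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "intensity (a.u.)")
  if (zoom) p <- p + ggplot2::coord_cartesian(xlim = c(2800, 3000))
  p
}

#' Dose-response plot of control-normalised values
#'
#' @param normalized A table with `membrane`, `conc`, `rel_value` (e.g. the
#'   `normalized` element of [run_full_pipeline()], filtered to one
#'   observable).
#' @return A ggplot of mean relative value (+/- SD) against concentration
#'   per membrane.
#' @export
plot_dose_response <- function(normalized) {
  summ <- normalized |>
    dplyr::group_by(.data$membrane, .data$conc) |>
    dplyr::summarise(m = mean(.data$rel_value), s = sd(.data$rel_value),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$conc, .data$m,
                                     colour = .data$membrane)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$s,
                                        ymax = .data$m + .data$s),
                           width = 0.5) +
    ggplot2::labs(x = "concentration (mM)", y = "value / control",
                  colour = NULL)
}

#' Autoplot method for droplet time series
#'
#' @param object A `droplet_timeseries`.
#' @param ... Unused.
#' @return A ggplot; see [plot_droplet_timeseries()].
#' @method autoplot droplet_timeseries
#' @export
autoplot.droplet_timeseries <- function(object, ...) {
  plot_droplet_timeseries(object)
}
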