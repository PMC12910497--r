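# Bilayer tensiometry for droplet interface bilayers.
#
# At mechanical equilibrium of the three-phase contact line the bilayer
# tension balances the two monolayer tensions pulling at the contact angle
# theta on either side: gamma_b = 2 * gamma_m * cos(theta). Degrees are the
# external unit throughout, matching tensiometer output.

#' Bilayer tension from monolayer tension and contact angle
#'
#' \eqn{\gamma_b = 2 \gamma_m \cos\theta}. Vectorised.
#'
#' @param gamma_m Monolayer (oil-water interface) tension, mN/m; positive.
#' @param theta_deg Contact angle in degrees, in `[0, 90)`. Angles at or
#'   above 90 describe a non-adherent droplet configuration and error.
#' @return Bilayer tension, mN/m.
#' @examples
#' bilayer_tension(1.125, 31.20) # 1.92 mN/m
#' @export
bilayer_tension <- function(gamma_m, theta_deg) {
  n <- max(length(gamma_m), length(theta_deg))
  gamma_m <- rep_len(as.numeric(gamma_m), n)
  theta_deg <- rep_len(as.numeric(theta_deg), n)
  if (any(!is.finite(gamma_m)) || any(gamma_m <= 0)) {
    abort("`gamma_m` must be positive.", class = "memphys_bad_measurement")
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg >= 90)) {
    abort("`theta_deg` must lie in [0, 90): theta >= 90 is a non-adherent configuration.",
          class = "memphys_no_bilayer")
  }
  2 * gamma_m * cos(theta_deg * pi / 180)
}

#' Contact angle implied by a bilayer/monolayer tension pair
#'
#' Inverse of [bilayer_tension()]: \eqn{\theta = \arccos(\gamma_b /
#' (2\gamma_m))}, degrees.
#'
#' @param gamma_b Bilayer tension, mN/m.
#' @inheritParams bilayer_tension
#' @return Contact angle, degrees.
#' @export
contact_angle_from_tensions <- function(gamma_m, gamma_b) {
  stopifnot(all(gamma_m > 0), all(gamma_b > 0), all(gamma_b <= 2 * gamma_m))
  acos(gamma_b / (2 * gamma_m)) * 180 / pi
}

#' Bilayer tension table with control normalisation
#'
#' Fills in the bilayer tension for every tensiometry record and normalises
#' it to the zero-concentration control of the same membrane
#' (\eqn{\gamma_b / \gamma_b^\circ}).
#'
#' @param records A data frame with columns `membrane`, `serotonin_mM`,
#'   `gamma_m_mN_m`, `theta_deg` (extra columns pass through). Exactly one
#'   record per membrane must have `serotonin_mM == 0`.
#' @param sd_gamma_m,sd_theta_deg Optional column names holding measurement
#'   SDs; when both are present a first-order propagated SD
#'   \eqn{\sigma_{\gamma_b}^2 = (2\cos\theta\,\sigma_{\gamma_m})^2 +
#'   (2\gamma_m\sin\theta\,\sigma_\theta)^2} is added as `gamma_b_sd`.
#' @param digits Decimal places for the reported `gamma_b_mN_m` column
#'   (`NULL` to disable rounding). The relative column is never rounded.
#' @return The input tibble with `gamma_b_mN_m` and `rel_gamma_b` added.
#' @examples
#' tension_table(data.frame(
#'   membrane = "DOPC", serotonin_mM = c(0, 40),
#'   gamma_m_mN_m = c(1.125, 0.664), theta_deg = c(31.20, 48.71)
#' ))
#' @export
tension_table <- function(records, sd_gamma_m = NULL, sd_theta_deg = NULL,
                          digits = 2) {
  stopifnot(is.data.frame(records),
            all(c("membrane", "serotonin_mM", "gamma_m_mN_m", "theta_deg") %in%
                  names(records)))
  out <- tibble::as_tibble(records)
  n_ctrl <- out |>
    dplyr::group_by(.data$membrane) |>
    dplyr::summarise(n0 = sum(.data$serotonin_mM == 0), .groups = "drop")
  if (any(n_ctrl$n0 != 1)) {
    abort(paste0("Each membrane needs exactly one control (serotonin_mM == 0) record; ",
                 "offending: ",
                 paste(n_ctrl$membrane[n_ctrl$n0 != 1], collapse = ", ")),
          class = "memphys_missing_control")
  }
  out <- dplyr::mutate(
    out, gamma_b_mN_m = bilayer_tension(.data$gamma_m_mN_m, .data$theta_deg))
  # round before normalising so the relative column matches what a reader
  # recomputes from the reported table
  if (!is.null(digits)) out$gamma_b_mN_m <- round(out$gamma_b_mN_m, digits)
  out <- out |>
    dplyr::group_by(.data$membrane) |>
    dplyr::mutate(rel_gamma_b = .data$gamma_b_mN_m /
                    .data$gamma_b_mN_m[.data$serotonin_mM == 0]) |>
    dplyr::ungroup()
  if (!is.null(sd_gamma_m) && !is.null(sd_theta_deg) &&
      all(c(sd_gamma_m, sd_theta_deg) %in% names(out))) {
    th <- out$theta_deg * pi / 180
    s_th <- out[[sd_theta_deg]] * pi / 180
    out$gamma_b_sd <- sqrt((2 * cos(th) * out[[sd_gamma_m]])^2 +
                             (2 * out$gamma_m_mN_m * sin(th) * s_th)^2)
  }
  out
}
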