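# Spherical-droplet and droplet-pair contact geometry.
#
# Two monolayer-coated droplets pressed together in oil adhere over a flat
# circular contact patch (the bilayer). Treating each droplet as a sphere of
# radius R_i with centre separation D, the patch is the common chord disk of
# the two circles seen in projection, and the DIB contact angle theta is the
# angle between each droplet's monolayer tangent and the bilayer plane at the
# contact line: sin(theta_i) = rc / R_i.

#' Volume of a spherical droplet from its diameter
#'
#' @param d Diameter(s), micrometres.
#' @return Volume(s) in cubic micrometres, \eqn{(\pi/6) d^3}.
#' @examples
#' sphere_volume_from_diameter(100)
#' @export
sphere_volume_from_diameter <- function(d) {
  if (!is.numeric(d) || length(d) == 0 || any(!is.finite(d)) || any(d <= 0)) {
    abort("`d` must be positive and finite: non-positive diameter is an invalid measurement.",
          class = "memphys_bad_measurement")
  }
  pi / 6 * d^3
}

#' Diameter of a spherical droplet from its volume
#'
#' Inverse of [sphere_volume_from_diameter()].
#' @param v Volume(s), cubic micrometres.
#' @return Diameter(s), micrometres.
#' @export
sphere_diameter_from_volume <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    abort("`v` must be positive and finite.", class = "memphys_bad_measurement")
  }
  (6 * v / pi)^(1 / 3)
}

#' Contact geometry of two adherent spherical droplets
#'
#' Vectorised over rows. Given droplet radii and the centre-to-centre
#' distance, computes the contact-patch radius from the standard two-circle
#' intersection chord, the per-droplet contact angles
#' \eqn{\theta_i = \arcsin(r_c / R_i)} and their mean, and the bilayer area
#' \eqn{A_b = \pi r_c^2}. With this convention \eqn{\theta \to 0} at
#' tangency, so \eqn{\gamma_b = 2\gamma_m\cos\theta} returns \eqn{2\gamma_m}
#' for a non-adherent pair.
#'
#' @param r1,r2 Droplet radii, micrometres.
#' @param d Centre-to-centre distance, micrometres. Circles must intersect:
#'   `abs(r1 - r2) < d < r1 + r2`; disjoint or nested pairs mean no bilayer
#'   formed and raise an error.
#' @return A tibble with columns `R1_um`, `R2_um`, `D_um`, `rc_um`,
#'   `theta_deg`, `Ab_um2`.
#' @examples
#' contact_geometry(50, 50, 50 * sqrt(3)) # rc = 25, theta = 30 deg
#' @export
contact_geometry <- function(r1, r2, d) {
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(as.numeric(r1), n)
  r2 <- rep_len(as.numeric(r2), n)
  d  <- rep_len(as.numeric(d), n)
  if (any(r1 <= 0) || any(r2 <= 0) || any(d <= 0)) {
    abort("Radii and centre distance must be positive.",
          class = "memphys_bad_measurement")
  }
  bad <- d >= r1 + r2 | d <= abs(r1 - r2)
  if (any(bad)) {
    abort(paste0(
      "No bilayer formed: droplet circles are disjoint or nested (need ",
      "|r1 - r2| < d < r1 + r2)."
    ), class = "memphys_no_bilayer")
  }
  # distance from centre 1 to the chord plane, then half-chord length
  a  <- (d^2 + r1^2 - r2^2) / (2 * d)
  rc <- sqrt(pmax(r1^2 - a^2, 0))
  theta <- (asin(pmin(rc / r1, 1)) + asin(pmin(rc / r2, 1))) / 2 * 180 / pi
  tibble::tibble(
    R1_um = r1, R2_um = r2, D_um = d,
    rc_um = rc, theta_deg = theta, Ab_um2 = pi * rc^2
  )
}

#' Contact geometry from two fitted circles
#'
#' Convenience wrapper around [contact_geometry()] for circles located in an
#' image plane, e.g. the output of [detect_droplet_pair()].
#'
#' @param circles A data frame with columns `cx`, `cy`, `r` (two rows) such
#'   as returned by [detect_droplet_pair()], in consistent length units.
#' @return A one-row tibble as from [contact_geometry()].
#' @export
contact_geometry_from_circles <- function(circles) {
  stopifnot(is.data.frame(circles), all(c("cx", "cy", "r") %in% names(circles)))
  if (nrow(circles) != 2) {
    abort("Exactly two circles are required.", class = "memphys_bad_measurement")
  }
  d <- sqrt(diff(circles$cx)^2 + diff(circles$cy)^2)
  contact_geometry(circles$r[1], circles$r[2], d)
}

#' Bilayer area implied by a contact angle
#'
#' For equal-sized droplets of radius `r` adhering at contact angle
#' `theta_deg`, the contact-patch radius is `r * sin(theta)` and the bilayer
#' area `pi * rc^2`.
#'
#' @param r Droplet radius, micrometres.
#' @param theta_deg Contact angle, degrees.
#' @return Bilayer area, square micrometres.
#' @export
bilayer_area_from_theta <- function(r, theta_deg) {
  stopifnot(r > 0, theta_deg > 0, theta_deg < 90)
  rc <- r * sin(theta_deg * pi / 180)
  pi * rc^2
}
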