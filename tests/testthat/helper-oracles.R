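# Independent oracles the implementation is checked against. These stay
# deliberately naive: fixed-step integration, dense sampling, enumeration
# and direct quadrature, sharing no code with the package internals.

# Fine-step explicit Euler integration of the two-droplet osmotic flux law.
# Diameters in um, osmolalities in mOsm/kg, area um^2, pf um/s.
euler_osmosis <- function(pf, times, d1, d2, osm1, osm2 = 0, area,
                          vw_um3 = 18.05e12, dt = 5e-4) {
  V1 <- pi / 6 * d1^3
  V2 <- pi / 6 * d2^3
  n1 <- osm1 * 1e-18 * V1
  n2 <- osm2 * 1e-18 * V2
  out <- matrix(NA_real_, length(times), 2)
  ti <- times[1]
  out[1, ] <- c(V1, V2)
  for (k in seq_along(times)[-1]) {
    while (ti < times[k] - 1e-12) {
      h <- min(dt, times[k] - ti)
      flux <- pf * vw_um3 * area * (n1 / V1 - n2 / V2)
      V1 <- V1 + h * flux
      V2 <- V2 - h * flux
      ti <- ti + h
    }
    out[k, ] <- c(V1, V2)
  }
  data.frame(t_s = times,
             d1_um = (6 * out[, 1] / pi)^(1 / 3),
             d2_um = (6 * out[, 2] / pi)^(1 / 3))
}

# Intersection of two circle boundaries by dense sampling: walk circle 1,
# find boundary points (numerically) on circle 2, take the two closest
# approaches as the chord endpoints.
circle_intersection_brute <- function(r1, r2, d, n = 2e6) {
  phi <- seq(0, 2 * pi, length.out = n)
  x <- r1 * cos(phi)
  y <- r1 * sin(phi)
  resid <- abs(sqrt((x - d)^2 + y^2) - r2)
  upper <- y > 0
  i1 <- which(upper)[which.min(resid[upper])]
  i2 <- which(!upper)[which.min(resid[!upper])]
  chord <- abs(y[i1] - y[i2])
  rc <- chord / 2
  theta <- (asin(rc / r1) + asin(rc / r2)) / 2 * 180 / pi
  list(rc = rc, theta_deg = theta)
}

# Balanced two-way sums of squares by direct enumeration of cell means.
brute_force_ss <- function(a, b, y) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  mA <- tapply(y, a, mean)
  mB <- tapply(y, b, mean)
  mAB <- tapply(y, interaction(a, b), mean)
  nA <- length(levels(a)); nB <- length(levels(b))
  n_cell <- length(y) / (nA * nB)
  ss_a <- nB * n_cell * sum((mA - gm)^2)
  ss_b <- nA * n_cell * sum((mB - gm)^2)
  ss_ab <- 0
  ss_res <- 0
  for (i in levels(a)) for (j in levels(b)) {
    sel <- a == i & b == j
    mij <- mean(y[sel])
    ss_ab <- ss_ab + n_cell * (mij - mA[[i]] - mB[[j]] + gm)^2
    ss_res <- ss_res + sum((y[sel] - mij)^2)
  }
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = unname(ss_ab),
       ss_res = ss_res, ss_tot = sum((y - gm)^2))
}

# Studentized range CDF by direct two-level quadrature:
# P(Q <= q) = int f_s(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where s is the scaled root of a chi-square with df degrees of freedom.
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q * s))^(k - 1)
    integrate(f, -9, 9, rel.tol = 1e-9)$value
  }
  lg <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  fs <- function(s) exp(lg + (df - 1) * log(s) - df * s^2 / 2)
  integrate(function(s) sapply(s, function(si) fs(si) * inner(si)),
            1e-4, 10, rel.tol = 1e-8)$value
}
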