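# Droplet-pair segmentation from grayscale micrographs.
#
# Raster convention: origin top-left, x rightward along columns, y downward
# along rows, lengths in pixels; a user-supplied um/px scale converts to
# physical units downstream.

#' Detect a pair of droplets in a grayscale image
#'
#' Segments two bright quasi-circular droplets on a darker background
#' (threshold, connected components, boundary extraction) and fits a circle
#' to each droplet boundary by algebraic (Kåsa) least squares refined with
#' Gauss-Newton passes. Adherent droplet pairs merge into a single connected
#' blob; in that case the blob boundary is split along its principal axis and
#' boundary pixels are iteratively reassigned to the nearer of the two fitted
#' circles, which recovers both arcs.
#'
#' @param image A numeric matrix of intensities (any range), or the path to
#'   an 8/16-bit grayscale PNG (read with the `png` package).
#' @param invert Set `TRUE` for dark droplets on a bright background.
#' @param smooth_sigma Gaussian pre-smoothing in pixels (0 disables); used
#'   to stabilise thresholding of noisy frames.
#' @param min_area Minimum component area (px) kept after thresholding.
#' @return A tibble with two rows (largest first) and columns `cx`, `cy`,
#'   `r` in pixels, plus `n_boundary`, the number of boundary pixels used.
#' @examples
#' img <- gen_droplet_image(r1 = 50, r2 = 50, d = 87, seed = 1)
#' detect_droplet_pair(img)
#' @export
detect_droplet_pair <- function(image, invert = FALSE, smooth_sigma = 2,
                                min_area = 50) {
  img <- read_gray_image(image)
  if (invert) img <- max(img) - img
  rng <- diff(range(img))
  if (!is.finite(rng) || rng <= .Machine$double.eps) {
    abort("Unusable frame: image has no contrast.", class = "memphys_bad_frame")
  }
  img01 <- (img - min(img)) / rng
  sm <- if (smooth_sigma > 0) {
    EBImage::gblur(EBImage::Image(img01), sigma = smooth_sigma)@.Data
  } else {
    img01
  }
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))@.Data
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0 || length(keep) > 2) {
    abort(sprintf("Unusable frame: expected 1 merged or 2 droplet components, found %d.",
                  length(keep)), class = "memphys_bad_frame")
  }
  circles <- if (length(keep) == 2) {
    purrr::map(keep, function(k) fit_circle(boundary_points(lab == k)))
  } else {
    split_merged_blob(boundary_points(lab == keep))
  }
  out <- dplyr::bind_rows(circles)
  # boundary pixel centres lie ~half a pixel inside the true disk edge
  out$r <- out$r + 0.5
  out <- out[order(-out$r), ]
  tibble::as_tibble(out)
}

# Matrix from path or passthrough. PNG via the png package (Suggests).
read_gray_image <- function(image) {
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Reading PNG files requires the `png` package.")
    }
    a <- png::readPNG(image)
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a)
  }
  stopifnot(is.matrix(image), is.numeric(image))
  image
}

# 4-connectivity boundary pixels of a logical mask, as (x, y) pixel centres.
boundary_points <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  nb <- m[1:nrow(mask), 2:(ncol(mask) + 1)] &
    m[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] &
    m[2:(nrow(mask) + 1), 1:ncol(mask)] &
    m[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  idx <- which(core & !nb, arr.ind = TRUE)
  # row index = y (downward), column index = x
  cbind(x = idx[, 2], y = idx[, 1])
}

# Kåsa algebraic circle fit + Gauss-Newton geometric refinement.
fit_circle <- function(pts, gn_iter = 3) {
  if (nrow(pts) < 3) abort("Too few boundary points for a circle fit.",
                           class = "memphys_bad_frame")
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  for (i in seq_len(gn_iter)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    di[di == 0] <- .Machine$double.eps
    J <- cbind(-dx / di, -dy / di, -1)
    res <- di - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  tibble::tibble(cx = cx, cy = cy, r = r, n_boundary = nrow(pts))
}

# Two circles from the boundary of one merged (peanut-shaped) blob.
split_merged_blob <- function(pts, n_iter = 8) {
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  u <- svd(cen, nu = 0, nv = 1)$v[, 1]       # principal axis
  s <- as.numeric(cen %*% u)
  groups <- list(pts[s <= 0, , drop = FALSE], pts[s > 0, , drop = FALSE])
  fits <- purrr::map(groups, fit_circle)
  for (i in seq_len(n_iter)) {
    d1 <- abs(sqrt((pts[, 1] - fits[[1]]$cx)^2 + (pts[, 2] - fits[[1]]$cy)^2) - fits[[1]]$r)
    d2 <- abs(sqrt((pts[, 1] - fits[[2]]$cx)^2 + (pts[, 2] - fits[[2]]$cy)^2) - fits[[2]]$r)
    g1 <- d1 < d2
    if (sum(g1) < 3 || sum(!g1) < 3) break
    new_fits <- list(fit_circle(pts[g1, , drop = FALSE]),
                     fit_circle(pts[!g1, , drop = FALSE]))
    if (max(abs(c(new_fits[[1]]$r - fits[[1]]$r, new_fits[[2]]$r - fits[[2]]$r))) < 1e-6) {
      fits <- new_fits
      break
    }
    fits <- new_fits
  }
  fits
}
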