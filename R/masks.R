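#' Generate a perturbed-ellipse nucleus mask
#'
#' Renders a binary mask for a single nucleus: an ellipse of the requested
#' mean radius and eccentricity whose boundary carries a low-order Fourier
#' ripple, so that downstream shell code is always exercised on
#' non-circular shapes. The ellipse axes are scaled so that the expected
#' area equals that of a circle with radius `radius_px`.
#'
#' @param radius_px mean radius in pixels (area-equivalent circle radius).
#' @param eccentricity ellipse eccentricity in `[0, 1)`; 0 gives a circle.
#' @param ripple_amp amplitude of the boundary ripple as a fraction of the
#'   local radius; 0 disables the perturbation.
#' @param ripple_order highest angular harmonic of the ripple (low orders
#'   give gentle lobes, as seen in fibroblast nuclei).
#' @param angle_rad orientation of the major axis.
#' @param seed optional RNG seed controlling the ripple phases/amplitudes.
#' @param pad background margin, in pixels, around the mask.
#' @return integer matrix (0 background / 1 foreground).
#' @examples
#' m <- make_nucleus_mask(30, eccentricity = 0.5, seed = 1)
#' sum(m) / (pi * 30^2)  # close to 1
#' @export
make_nucleus_mask <- function(radius_px, eccentricity = 0, ripple_amp = 0.04,
                              ripple_order = 3, angle_rad = 0, seed = NULL,
                              pad = 3) {
  stopifnot(radius_px >= 3, eccentricity >= 0, eccentricity < 1,
            ripple_amp >= 0, ripple_amp < 0.5)
  with_seed(seed, {
    q <- sqrt(1 - eccentricity^2)      # axis ratio b/a
    a <- radius_px / sqrt(q)
    b <- radius_px * sqrt(q)
    ks <- if (ripple_amp > 0 && ripple_order >= 2) 2:ripple_order else integer()
    amps <- if (length(ks)) runif(length(ks), 0, ripple_amp) else numeric()
    phis <- if (length(ks)) runif(length(ks), 0, 2 * pi) else numeric()
    half <- ceiling(max(a, b) * (1 + ripple_amp * max(1, length(ks)))) + pad
    n <- 2L * half + 1L
    cr <- cc <- half + 1L
    dr <- row(matrix(0, n, n)) - cr
    dc <- col(matrix(0, n, n)) - cc
    # rotate into ellipse frame
    u <- cos(angle_rad) * dc + sin(angle_rad) * dr
    v <- -sin(angle_rad) * dc + cos(angle_rad) * dr
    rho <- sqrt((u / a)^2 + (v / b)^2)
    theta <- atan2(v, u)
    lim <- 1
    for (i in seq_along(ks)) lim <- lim + amps[i] * cos(ks[i] * theta + phis[i])
    mask <- matrix(as.integer(rho <= lim), n, n)
    # keep the largest component in case extreme ripples pinch off pixels
    lab <- EBImage::bwlabel(as_mask(mask))
    if (max(lab) > 1) {
      keep <- which.max(tabulate(lab[lab > 0]))
      mask <- matrix(as.integer(lab == keep), n, n)
    }
    mask
  })
}

# Euclidean distance from every foreground pixel to the nearest background
# pixel; the image border counts as background (masks are padded before the
# transform so border-touching objects get finite distances).
boundary_distance <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- as_mask(mask)
  p <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  d <- EBImage::distmap(p)
  as.matrix(d)[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
}
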