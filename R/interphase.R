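#' Specification of a synthetic interphase scene
#'
#' Collects the generator parameters for an interphase FISH image: number
#' of nuclei, nucleus geometry, the probe configuration (two territories
#' per probe in a diploid nucleus, three pooled BAC spots per territory by
#' default, emulating pooled probe sets used to boost interphase signal),
#' the radial placement model, and the imaging noise model.
#'
#' The noise model is `list(background, sd, blur_sigma)`: a constant
#' background offset (DN), additive Gaussian read noise (DN, clamped at 0)
#' and a Gaussian optical blur applied to both channels. `noise = 0` is
#' shorthand for a noise-free, blur-free scene.
#'
#' Territories are identity groupings of spots: every spot is drawn
#' independently from the placement model, so the generating radial
#' distribution is exactly the model — the property the measurement
#' oracles rely on. Spatial clustering of spots within a territory is not
#' modelled.
#'
#' @param n_nuclei number of nuclei to place (>= 1).
#' @param nucleus_radius_px `c(mean, sd)` of the nucleus radius.
#' @param nucleus_eccentricity `c(min, max)` eccentricity range in `[0, 1)`.
#' @param territories_per_probe territories per nucleus (2 = diploid).
#' @param spots_per_territory spots per territory (3 = pooled BAC triple).
#' @param placement a [radial_placement()] model.
#' @param noise `list(background, sd, blur_sigma)` or a single 0.
#' @param spot_sigma Gaussian spot radius (px) in the probe channel.
#' @param spot_intensity peak spot intensity (DN).
#' @param nucleus_intensity counterstain intensity inside nuclei (DN).
#' @param pixel_size_um pixel size metadata (um).
#' @param allow_border_clipping may nuclei overlap the image edge?
#' @param image_size `c(rows, cols)`, computed from `n_nuclei` when `NULL`.
#' @return object of class `interphase_spec`.
#' @export
interphase_spec <- function(n_nuclei,
                            nucleus_radius_px = c(mean = 40, sd = 4),
                            nucleus_eccentricity = c(0, 0.4),
                            territories_per_probe = 2L,
                            spots_per_territory = 3L,
                            placement = radial_placement("uniform_area"),
                            noise = list(background = 5, sd = 2,
                                         blur_sigma = 1),
                            spot_sigma = 1.5, spot_intensity = 3000,
                            nucleus_intensity = 8000, pixel_size_um = 0.1,
                            allow_border_clipping = FALSE,
                            image_size = NULL) {
  if (identical(noise, 0)) noise <- list(background = 0, sd = 0, blur_sigma = 0)
  noise <- modifyList(list(background = 0, sd = 0, blur_sigma = 0), noise)
  stopifnot(n_nuclei >= 1, length(nucleus_radius_px) == 2,
            nucleus_radius_px[1] >= 8, nucleus_radius_px[2] >= 0,
            all(nucleus_eccentricity >= 0), all(nucleus_eccentricity < 1),
            territories_per_probe >= 1, spots_per_territory >= 1,
            inherits(placement, "radial_placement"),
            noise$background >= 0, noise$sd >= 0, noise$blur_sigma >= 0,
            spot_sigma > 0, spot_intensity > 0, nucleus_intensity > 0)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = unname(nucleus_radius_px),
                 nucleus_eccentricity = sort(unname(nucleus_eccentricity)),
                 territories_per_probe = as.integer(territories_per_probe),
                 spots_per_territory = as.integer(spots_per_territory),
                 placement = placement, noise = noise,
                 spot_sigma = spot_sigma, spot_intensity = spot_intensity,
                 nucleus_intensity = nucleus_intensity,
                 pixel_size_um = pixel_size_um,
                 allow_border_clipping = isTRUE(allow_border_clipping),
                 image_size = image_size),
            class = "interphase_spec")
}

# add a Gaussian blob at 1-based (r0, c0); window cut at 4 sigma
add_spot <- function(img, r0, c0, sigma, peak) {
  w <- ceiling(4 * sigma)
  rs <- max(1, r0 - w):min(nrow(img), r0 + w)
  cs <- max(1, c0 - w):min(ncol(img), c0 + w)
  blob <- peak * exp(-(outer((rs - r0)^2, (cs - c0)^2, "+")) / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + blob
  img
}

apply_noise <- function(mat, noise) {
  if (noise$blur_sigma > 0)
    mat <- as.matrix(EBImage::gblur(mat, sigma = noise$blur_sigma,
                                    boundary = 0))
  mat <- mat + noise$background
  if (noise$sd > 0) mat <- mat + rnorm(length(mat), 0, noise$sd)
  pmax(mat, 0)
}

#' Render a synthetic interphase FISH scene
#'
#' Places `n_nuclei` non-overlapping perturbed-ellipse nuclei, draws probe
#' spots inside each according to the placement model, renders a DAPI
#' counterstain channel and a probe channel, applies blur and noise, and
#' returns the image together with a full ground-truth record (per-nucleus
#' masks' shell decomposition at generation time and every spot's
#' coordinates and shell index). Identical `spec` + `seed` give
#' bit-identical output.
#'
#' @param spec an [interphase_spec()].
#' @param seed RNG seed (required; the generator has no hidden RNG state).
#' @param n_shells_truth number of equal-area shells used to record each
#'   spot's ground-truth shell index (default 5).
#' @return list with `image` ([multichannel_image()] with channels `dapi`
#'   and `probe`), `truth` (list: `nuclei` data.frame, `spots` data.frame
#'   with 1-based `row`/`col` and `shell_index`), `spec`, `seed`.
#' @export
render_interphase_scene <- function(spec, seed, n_shells_truth = 5L) {
  stopifnot(inherits(spec, "interphase_spec"))
  with_seed(seed, {
    rmean <- spec$nucleus_radius_px[1]; rsd <- spec$nucleus_radius_px[2]
    side <- if (!is.null(spec$image_size)) spec$image_size
            else rep(ceiling(sqrt(spec$n_nuclei) * 3.4 * rmean) + 20L, 2L)
    if (length(side) == 1) side <- rep(side, 2)
    dapi <- matrix(0, side[1], side[2])
    probe <- matrix(0, side[1], side[2])

    # sample nucleus geometry first, then place by bounding circle
    radii <- pmax(8, rnorm(spec$n_nuclei, rmean, rsd))
    eccs <- runif(spec$n_nuclei, spec$nucleus_eccentricity[1],
                  spec$nucleus_eccentricity[2])
    centers <- matrix(NA_real_, spec$n_nuclei, 2)
    bound <- radii / (1 - eccs^2)^0.25 * 1.12   # major semi-axis + ripple slack
    for (i in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        if (spec$allow_border_clipping) {
          ctr <- c(runif(1, 1, side[1]), runif(1, 1, side[2]))
        } else {
          lo <- bound[i] + 2
          if (side[1] - lo <= lo || side[2] - lo <= lo)
            stop("placement error: image too small for nucleus radius")
          ctr <- c(runif(1, lo, side[1] - lo), runif(1, lo, side[2] - lo))
        }
        if (i == 1 || all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
              matrix(ctr, i - 1, 2, byrow = TRUE))^2)) >
              bound[i] + bound[seq_len(i - 1)] + 2)) {
          centers[i, ] <- ctr; placed <- TRUE; break
        }
      }
      if (!placed) stop("placement error: could not place nucleus ", i,
                        " without overlap")
    }

    nuclei <- data.frame(nucleus_id = integer(), center_row = numeric(),
                         center_col = numeric(), radius_px = numeric(),
                         eccentricity = numeric(), area_px = integer(),
                         clipped = logical())
    spots_all <- NULL
    n_spots <- spec$territories_per_probe * spec$spots_per_territory
    for (i in seq_len(spec$n_nuclei)) {
      mask <- make_nucleus_mask(radii[i], eccs[i],
                                angle_rad = runif(1, 0, pi),
                                seed = NULL)  # RNG already seeded
      half <- (nrow(mask) - 1L) %/% 2L
      r0 <- round(centers[i, 1]); c0 <- round(centers[i, 2])
      rs <- (r0 - half):(r0 + half); cs <- (c0 - half):(c0 + half)
      rkeep <- rs >= 1 & rs <= side[1]; ckeep <- cs >= 1 & cs <= side[2]
      clipped <- !all(rkeep) || !all(ckeep)
      sub <- mask[rkeep, ckeep, drop = FALSE]
      dapi[rs[rkeep], cs[ckeep]] <- dapi[rs[rkeep], cs[ckeep]] +
        spec$nucleus_intensity * sub
      # ground truth uses the unclipped mask geometry
      shells <- compute_shells(mask, n_shells_truth, "equal_area")
      pos <- sample_radial_positions(mask, spec$placement, n_spots,
                                     seed = NULL, shells = if (spec$placement$kind ==
                                       "shell_weights") compute_shells(mask,
                                       length(spec$placement$shell_weights),
                                       "equal_area") else NULL)
      si <- shell_at(shells, pos)
      abs_r <- pos$row + r0 - half - 1L
      abs_c <- pos$col + c0 - half - 1L
      inside <- abs_r >= 1 & abs_r <= side[1] & abs_c >= 1 & abs_c <= side[2]
      for (k in which(inside))
        probe <- add_spot(probe, abs_r[k], abs_c[k], spec$spot_sigma,
                          spec$spot_intensity)
      nuclei <- rbind(nuclei, data.frame(nucleus_id = i,
        center_row = r0, center_col = c0, radius_px = radii[i],
        eccentricity = eccs[i], area_px = sum(sub), clipped = clipped))
      spots_all <- rbind(spots_all, data.frame(nucleus_id = i,
        territory = rep(seq_len(spec$territories_per_probe),
                        each = spec$spots_per_territory),
        channel = "probe", row = abs_r, col = abs_c, shell_index = si,
        rendered = inside))
    }
    dapi <- apply_noise(dapi, spec$noise)
    probe <- apply_noise(probe, spec$noise)
    img <- multichannel_image(list(dapi = dapi, probe = probe),
                              pixel_size_um = spec$pixel_size_um,
                              metadata = list(scene = "interphase",
                                              seed = seed))
    list(image = img, truth = list(nuclei = nuclei, spots = spots_all),
         spec = spec, seed = seed)
  })
}
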