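# rasterize a rod: pixels within width/2 of the segment from p1 to p2
rod_pixels <- function(center, angle, length_px, width_px, side) {
  half <- length_px / 2
  dvec <- c(sin(angle), cos(angle))            # (row, col) direction
  p1 <- center - half * dvec; p2 <- center + half * dvec
  rr <- floor(min(p1[1], p2[1]) - width_px):ceiling(max(p1[1], p2[1]) + width_px)
  cc <- floor(min(p1[2], p2[2]) - width_px):ceiling(max(p1[2], p2[2]) + width_px)
  rr <- rr[rr >= 1 & rr <= side[1]]; cc <- cc[cc >= 1 & cc <= side[2]]
  if (!length(rr) || !length(cc)) return(NULL)
  g <- expand.grid(row = rr, col = cc)
  # distance from each candidate pixel to the segment
  ap_r <- g$row - p1[1]; ap_c <- g$col - p1[2]
  ab_r <- p2[1] - p1[1]; ab_c <- p2[2] - p1[2]
  t <- pmin(pmax((ap_r * ab_r + ap_c * ab_c) / (ab_r^2 + ab_c^2), 0), 1)
  dr <- ap_r - t * ab_r; dc <- ap_c - t * ab_c
  keep <- sqrt(dr^2 + dc^2) <= width_px / 2
  list(row = g$row[keep], col = g$col[keep], t = t[keep])
}

# position of a fused segment along its chromosome: a chromosome carrying
# m labels is split lengthwise; label i occupies [ (i-1)/m, i/m ] with the
# macro's own label first, so fused micros sit toward the distal end
segment_fraction_range <- function(content, label) {
  i <- match(label, content)
  m <- length(content)
  c((i - 1) / m, i / m)
}

#' Render a synthetic metaphase spread with a two-colour probe pair
#'
#' Draws `diploid_number` rod-shaped chromosomes (two copies of each
#' chromosome type, random position and orientation, non-overlapping with
#' bounded retries) into a DAPI channel, then renders the two probes of a
#' probe pair as Gaussian spots: each probe produces one spot per copy of
#' the chromosome type whose homolog content carries its GGA label — two
#' spots per spread — and zero spots when the label is listed among the
#' species' probe failures. Probe A is rendered in the `fitc` channel and
#' probe B in `texasred`. When both probes carry the same label (the
#' orientation design with one BAC near each chromosome end) the FITC spot
#' is placed near one rod end and the Texas Red spot near the other.
#'
#' @param karyotype a [karyotype_model()].
#' @param probe_pair character vector of 1 or 2 GGA labels,
#'   e.g. `c("GGA18", "GGA24")` or `c("GGA24", "GGA24")`.
#' @param seed RNG seed.
#' @param noise `list(background, sd, blur_sigma)` or 0 (as in
#'   [interphase_spec()]).
#' @param chrom_width_px rod width.
#' @param chrom_intensity counterstain intensity on chromosomes (DN).
#' @param spot_sigma,spot_intensity Gaussian spot shape (px) and peak (DN).
#' @param image_size image side(s) in px; scaled to total chromosome area
#'   when `NULL`.
#' @return list with `image` (channels `dapi`, `fitc`, `texasred`),
#'   `truth` (list: `objects` data.frame of rendered chromosomes, `spots`
#'   data.frame), `karyotype`, `probe_pair`, `seed`.
#' @export
render_metaphase_scene <- function(karyotype, probe_pair, seed,
                                   noise = list(background = 5, sd = 2,
                                                blur_sigma = 1),
                                   chrom_width_px = 5,
                                   chrom_intensity = 8000,
                                   spot_sigma = 1.2, spot_intensity = 12000,
                                   image_size = NULL) {
  stopifnot(inherits(karyotype, "karyotype_model"),
            length(probe_pair) %in% 1:2)
  if (length(probe_pair) == 1) probe_pair <- rep(probe_pair, 2)
  if (identical(noise, 0)) noise <- list(background = 0, sd = 0, blur_sigma = 0)
  noise <- modifyList(list(background = 0, sd = 0, blur_sigma = 0), noise)
  known <- c(unlist(karyotype$chromosomes$content), karyotype$probe_failures)
  for (lb in probe_pair)
    if (!lb %in% known)
      stop("configuration error: probe label '", lb,
           "' not in karyotype '", karyotype$species, "'")

  with_seed(seed, {
    chrom <- karyotype$chromosomes
    total_area <- 2 * sum(chrom$length_px * chrom_width_px)
    side <- if (!is.null(image_size)) image_size
            else rep(max(400L, ceiling(sqrt(total_area * 16))), 2L)
    if (length(side) == 1) side <- rep(side, 2)
    dapi <- matrix(0, side[1], side[2])
    occupied <- matrix(FALSE, side[1], side[2])

    # place large chromosomes first; 2 copies per type
    ord <- order(-chrom$length_px)
    objects <- NULL
    obj_pix <- list()
    label_img <- matrix(0L, side[1], side[2])
    oid <- 0L
    for (ti in ord) for (copy in 1:2) {
      len <- chrom$length_px[ti]
      placed <- FALSE
      for (try in seq_len(600L)) {
        margin <- len / 2 + chrom_width_px + 2
        ctr <- c(runif(1, margin, side[1] - margin),
                 runif(1, margin, side[2] - margin))
        ang <- runif(1, 0, pi)
        px <- rod_pixels(ctr, ang, len, chrom_width_px, side)
        if (is.null(px) || !length(px$row)) next
        lin <- cbind(px$row, px$col)
        # 2 px clearance via a dilated check window
        ok <- TRUE
        rmin <- max(1, min(px$row) - 4); rmax <- min(side[1], max(px$row) + 4)
        cmin <- max(1, min(px$col) - 4); cmax <- min(side[2], max(px$col) + 4)
        if (any(occupied[rmin:rmax, cmin:cmax])) {
          # fine check: any occupied pixel within 2 px of the new rod
          occ <- which(occupied[rmin:rmax, cmin:cmax], arr.ind = TRUE)
          if (nrow(occ) > 0) {
            occ[, 1] <- occ[, 1] + rmin - 1L; occ[, 2] <- occ[, 2] + cmin - 1L
            dmin <- min(vapply(seq_len(nrow(occ)), function(j)
              min((occ[j, 1] - px$row)^2 + (occ[j, 2] - px$col)^2),
              numeric(1)))
            ok <- dmin > 12.25   # 3.5 px clearance so smoothing cannot bridge
          }
        }
        if (ok) {
          oid <- oid + 1L
          dapi[lin] <- chrom_intensity
          occupied[lin] <- TRUE
          label_img[lin] <- oid
          obj_pix[[oid]] <- px
          objects <- rbind(objects, data.frame(object_id = oid, type = ti,
            copy = copy, length_px = len, class = chrom$class[ti],
            labels = paste(chrom$content[[ti]], collapse = "+"),
            center_row = ctr[1], center_col = ctr[2], angle = ang))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement error: could not place chromosome type ", ti,
             " copy ", copy, " without overlap")
    }

    fitc <- matrix(0, side[1], side[2])
    texasred <- matrix(0, side[1], side[2])
    spots <- NULL
    chans <- c("fitc", "texasred")
    same_label <- probe_pair[1] == probe_pair[2]
    for (pi in 1:2) {
      lb <- probe_pair[pi]
      if (lb %in% karyotype$probe_failures) next
      ti <- type_of_label(karyotype, lb)
      if (is.na(ti)) next
      targets <- objects[objects$type == ti, , drop = FALSE]
      for (j in seq_len(nrow(targets))) {
        ob <- targets[j, ]
        frange <- segment_fraction_range(chrom$content[[ti]], lb)
        if (same_label)  # end probes: opposite ends of the same rod
          frange <- if (pi == 1) c(0.02, 0.15) else c(0.85, 0.98)
        f <- runif(1, frange[1] + 0.02, frange[2] - 0.02)
        dvec <- c(sin(ob$angle), cos(ob$angle))
        pos <- c(ob$center_row, ob$center_col) +
          (f - 0.5) * ob$length_px * dvec
        r0 <- round(pos[1]); c0 <- round(pos[2])
        ch <- chans[pi]
        if (ch == "fitc") fitc <- add_spot(fitc, r0, c0, spot_sigma,
                                           spot_intensity)
        else texasred <- add_spot(texasred, r0, c0, spot_sigma,
                                  spot_intensity)
        spots <- rbind(spots, data.frame(channel = ch, probe = lb,
          row = r0, col = c0, object_id = ob$object_id, type = ti))
      }
    }
    dapi <- apply_noise(dapi, noise)
    fitc <- apply_noise(fitc, noise)
    texasred <- apply_noise(texasred, noise)
    img <- multichannel_image(list(dapi = dapi, fitc = fitc,
                                   texasred = texasred),
                              metadata = list(scene = "metaphase",
                                              species = karyotype$species,
                                              seed = seed))
    list(image = img,
         truth = list(objects = objects, spots = spots,
                      label_image = label_img),
         karyotype = karyotype, probe_pair = probe_pair, seed = seed)
  })
}
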