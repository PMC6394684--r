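# shared threshold + label core for counterstain segmentation
segment_binary <- function(channel, smoothing_sigma, threshold_method,
                           fill_holes, min_area_px) {
  if (!is.matrix(channel) || length(channel) == 0)
    stop("input error: channel must be a non-empty matrix")
  if (!all(is.finite(channel)))
    stop("input error: channel contains non-finite pixels")
  rng <- range(channel)
  if (rng[2] <= rng[1])           # constant image: nothing to segment
    return(matrix(0L, nrow(channel), ncol(channel)))
  sm <- if (smoothing_sigma > 0)
    as.matrix(EBImage::gblur(channel, sigma = smoothing_sigma, boundary = 0))
  else channel
  if (is.numeric(threshold_method)) {
    th <- threshold_method
  } else if (identical(threshold_method, "otsu")) {
    norm <- (sm - min(sm)) / (max(sm) - min(sm))
    th <- min(sm) + EBImage::otsu(EBImage::Image(norm)) * (max(sm) - min(sm))
  } else stop("unknown threshold_method: ", threshold_method)
  mask <- sm > th
  if (sum(mask) == 0) return(matrix(0L, nrow(channel), ncol(channel)))
  lab <- EBImage::bwlabel(as_mask(mask))
  if (fill_holes) lab <- EBImage::fillHull(lab)
  lab <- as.matrix(lab)
  # drop small objects, relabel consecutively
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

# crack-length perimeter per label with the Cauchy-Crofton correction
# (pi/4 x count of exposed 4-neighbour pixel edges), which is unbiased for
# smooth convex outlines: a rasterized disc gets 2*pi*r, hence
# circularity 1
label_perimeters <- function(label_img) {
  n <- max(label_img)
  p <- matrix(0L, nrow(label_img) + 2L, ncol(label_img) + 2L)
  p[2:(nrow(label_img) + 1L), 2:(ncol(label_img) + 1L)] <- label_img
  core <- p[2:(nrow(label_img) + 1L), 2:(ncol(label_img) + 1L)]
  cracks <- numeric(n)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- p[2:(nrow(label_img) + 1L) + sh[1], 2:(ncol(label_img) + 1L) + sh[2]]
    exposed <- core > 0 & nb != core
    cracks <- cracks + tabulate(core[exposed], nbins = n)
  }
  cracks * pi / 4
}

# feature table for a consecutive label image
object_table <- function(label_img) {
  n <- max(label_img)
  if (n == 0)
    return(data.frame(label = integer(), area_px = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      perimeter_px = numeric(), circularity = numeric(),
                      touches_border = logical()))
  idx <- which(label_img > 0)
  rr <- (idx - 1L) %% nrow(label_img) + 1L
  cc <- (idx - 1L) %/% nrow(label_img) + 1L
  lb <- label_img[idx]
  area <- tabulate(lb, nbins = n)
  per <- label_perimeters(label_img)
  border <- rr == 1L | rr == nrow(label_img) | cc == 1L | cc == ncol(label_img)
  touches <- vapply(seq_len(n), function(i) any(border[lb == i]), logical(1))
  data.frame(label = seq_len(n),
             area_px = area,
             centroid_row = vapply(seq_len(n), function(i) mean(rr[lb == i]),
                                   numeric(1)),
             centroid_col = vapply(seq_len(n), function(i) mean(cc[lb == i]),
                                   numeric(1)),
             perimeter_px = per,
             circularity = pmin(4 * pi * area / pmax(per, 1)^2, 1.5),
             touches_border = touches)
}

new_nucleus_set <- function(label_img, objects) {
  structure(list(label_image = label_img, objects = objects),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat("<nucleus_set> ", nrow(x$objects), " object(s)\n", sep = "")
  if (nrow(x$objects) > 0) print(utils::head(x$objects, 10))
  invisible(x)
}

#' Segment nuclei from a counterstain channel
#'
#' Gaussian smoothing, global thresholding (Otsu by default), hole
#' filling, connected-component labelling and a minimum-area filter.
#' Touching nuclei are *not* split; merged objects are expected to be
#' rejected downstream by the area/circularity filter
#' ([filter_nuclei()]). An all-zero (or constant) channel yields an empty
#' set, not an error.
#'
#' @param channel 2D counterstain intensity grid.
#' @param threshold_method `"otsu"` or a numeric absolute threshold.
#' @param min_area_px discard components smaller than this.
#' @param smoothing_sigma Gaussian pre-smoothing sigma (px).
#' @return object of class `nucleus_set`: `label_image` (0 = background,
#'   consecutive positive labels) and `objects` (label, area, centroid,
#'   perimeter, circularity `4*pi*A/P^2`, border flag).
#' @export
segment_counterstain <- function(channel, threshold_method = "otsu",
                                 min_area_px = 200, smoothing_sigma = 2) {
  lab <- segment_binary(channel, smoothing_sigma, threshold_method,
                        fill_holes = TRUE, min_area_px = min_area_px)
  new_nucleus_set(lab, object_table(lab))
}

#' Quality-filter a segmented nucleus set
#'
#' Retains objects within an area window, above a circularity cutoff and
#' (optionally) not touching the image border, then relabels consecutively.
#' Rejected objects and their reasons are kept in the `rejected` attribute
#' for reporting. Filtering is idempotent: re-applying the same parameters
#' changes nothing.
#'
#' @param nuclei a `nucleus_set`.
#' @param min_area_px,max_area_px inclusive area window (px).
#' @param min_circularity minimum `4*pi*A/P^2`; the default 0.6 admits
#'   elliptical fibroblast nuclei while rejecting merged pairs.
#' @param exclude_border drop objects with any pixel on the image edge?
#' @return filtered `nucleus_set` (with attribute `rejected`).
#' @export
filter_nuclei <- function(nuclei, min_area_px = 0, max_area_px = Inf,
                          min_circularity = 0.6, exclude_border = TRUE) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  if (min_area_px > max_area_px)
    stop("parameter error: min_area_px > max_area_px")
  ob <- nuclei$objects
  reason <- rep("", nrow(ob))
  reason[ob$area_px < min_area_px] <- "too_small"
  reason[ob$area_px > max_area_px] <- "too_large"
  reason[reason == "" & ob$circularity < min_circularity] <- "not_circular"
  if (exclude_border)
    reason[reason == "" & ob$touches_border] <- "touches_border"
  keep <- which(reason == "")
  remap <- integer(nrow(ob)); remap[keep] <- seq_along(keep)
  lab <- nuclei$label_image
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  kept <- ob[keep, , drop = FALSE]
  kept$label <- seq_along(keep)
  rownames(kept) <- NULL
  res <- new_nucleus_set(out, kept)
  rej <- ob[reason != "", , drop = FALSE]
  rej$reason <- reason[reason != ""]
  attr(res, "rejected") <- rej
  res
}

# extract the binary mask of one labelled object, cropped with padding;
# returns the mask plus its offset in the scene (for mapping coordinates)
object_mask <- function(set, label, pad = 3L) {
  idx <- which(set$label_image == label)
  if (!length(idx)) stop("no such label: ", label)
  nr <- nrow(set$label_image)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  r0 <- min(rr) - pad; c0 <- min(cc) - pad
  m <- matrix(0L, max(rr) - min(rr) + 1L + 2L * pad,
              max(cc) - min(cc) + 1L + 2L * pad)
  m[cbind(rr - r0, cc - c0)] <- 1L
  list(mask = m, row_offset = r0, col_offset = c0)
}

#' Segment chromosomes from a metaphase spread
#'
#' Same threshold/label machinery as [segment_counterstain()] but tuned
#' for small rod-shaped objects (no hole filling, smaller default area
#' cutoff, lighter smoothing). Objects whose area exceeds
#' `outlier_mult` times the 90th percentile of object areas are flagged
#' as area outliers — the signature of two overlapping chromosomes merged
#' into one component.
#'
#' @param counterstain 2D DAPI grid of the spread.
#' @param threshold_method `"otsu"` or numeric threshold.
#' @param min_area_px minimum object area.
#' @param smoothing_sigma Gaussian pre-smoothing sigma.
#' @param outlier_mult area-outlier multiplier.
#' @return object of class `chromosome_set`: `label_image`, `objects`
#'   (label, area, centroid, `length_px` estimate from the major axis,
#'   `area_outlier` flag).
#' @export
segment_chromosomes <- function(counterstain, threshold_method = "otsu",
                                min_area_px = 20, smoothing_sigma = 1,
                                outlier_mult = 1.5) {
  lab <- segment_binary(counterstain, smoothing_sigma, threshold_method,
                        fill_holes = FALSE, min_area_px = min_area_px)
  ob <- object_table(lab)
  n <- nrow(ob)
  len <- numeric(n)
  if (n > 0) {
    fm <- EBImage::computeFeatures.moment(lab)
    # major axis of the equivalent second-moment ellipse
    len <- fm[, "m.majoraxis"]
    ob$length_px <- len
    # baseline excludes the largest object so a merged giant cannot mask
    # itself; with a single object nothing is flagged
    if (n > 1) {
      baseline <- quantile(ob$area_px[-which.max(ob$area_px)], 0.9,
                           names = FALSE, type = 7)
      ob$area_outlier <- ob$area_px > outlier_mult * baseline
    } else ob$area_outlier <- FALSE
  } else {
    ob$length_px <- numeric(0)
    ob$area_outlier <- logical(0)
  }
  structure(list(label_image = lab, objects = ob),
            class = "chromosome_set")
}

#' @export
print.chromosome_set <- function(x, ...) {
  cat("<chromosome_set> ", nrow(x$objects), " object(s), ",
      sum(x$objects$area_outlier), " area outlier(s)\n", sep = "")
  invisible(x)
}
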