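#' Detect FISH spots in a probe channel
#'
#' Finds local intensity maxima above an absolute threshold, applies
#' greedy non-maximum suppression so no two retained spots are closer than
#' `min_separation_px` (the brighter spot wins; exact ties resolve by
#' (row, col) order), and assigns each spot the chromosome (or nucleus)
#' label under its coordinate. Zero spots is a valid outcome — probes can
#' legitimately fail to hybridize in a species.
#'
#' @param channel 2D probe intensity grid.
#' @param chromosomes optional `chromosome_set` (or any object with a
#'   `label_image`) used for spot assignment; spots over background get
#'   label 0 (`unassigned`).
#' @param min_intensity absolute peak threshold (DN).
#' @param min_separation_px minimum centre-to-centre spot distance.
#' @return data.frame with 1-based `row`, `col`, `intensity`, `label`
#'   (0 = unassigned), `assigned` flag; one row per retained spot, ordered
#'   by decreasing intensity.
#' @export
detect_spots <- function(channel, chromosomes = NULL, min_intensity = 500,
                         min_separation_px = 5) {
  if (!is.matrix(channel)) stop("channel must be a matrix")
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  w <- max(1L, as.integer(floor(min_separation_px / 2)))
  brush <- matrix(1, 2L * w + 1L, 2L * w + 1L)
  mx <- as.matrix(EBImage::dilate(EBImage::Image(channel /
    max(channel, 1)), brush)) * max(channel, 1)
  cand <- which(channel >= min_intensity & channel >= mx - 1e-9)
  if (!length(cand))
    return(data.frame(row = integer(), col = integer(),
                      intensity = numeric(), label = integer(),
                      assigned = logical()))
  nr <- nrow(channel)
  rr <- (cand - 1L) %% nr + 1L
  cc <- (cand - 1L) %/% nr + 1L
  iv <- channel[cand]
  ord <- order(-iv, rr, cc)
  rr <- rr[ord]; cc <- cc[ord]; iv <- iv[ord]
  keep <- logical(length(rr))
  for (i in seq_along(rr)) {
    if (i == 1 || all((rr[keep][seq_len(sum(keep))] - rr[i])^2 +
                      (cc[keep][seq_len(sum(keep))] - cc[i])^2 >=
                      min_separation_px^2)) keep[i] <- TRUE
  }
  rr <- rr[keep]; cc <- cc[keep]; iv <- iv[keep]
  lab <- rep(0L, length(rr))
  if (!is.null(chromosomes)) {
    li <- if (is.matrix(chromosomes)) chromosomes else chromosomes$label_image
    lab <- li[cbind(rr, cc)]
  }
  data.frame(row = rr, col = cc, intensity = iv, label = as.integer(lab),
             assigned = lab > 0L)
}
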