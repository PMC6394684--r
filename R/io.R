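#' Multi-channel image container
#'
#' A minimal container for registered single-plane fluorescence channels:
#' a named list of same-sized, non-negative, finite intensity matrices plus
#' pixel-size metadata. Intensities are arbitrary detector units (DN) in
#' `[0, 65535]`; matrices are indexed `[row, col]` with the origin at the
#' top-left.
#'
#' @param channels named list of numeric matrices, identical dimensions.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param metadata free-form named list.
#' @return object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_um = 0.1,
                               metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("all channels must be matrices")
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("all channels must share identical dimensions")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!all(is.finite(v)) || any(v < 0))
      stop("channel '", ch, "' has non-finite or negative intensities")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 metadata = metadata), class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<multichannel_image> ", d[1], "x", d[2], " px, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "),
      " (pixel ", x$pixel_size_um, " um)\n", sep = "")
  invisible(x)
}

#' Read / write multi-channel TIFF images
#'
#' Images are stored as multi-page 16-bit grayscale TIFF (one page per
#' channel); channel names, pixel size and metadata travel in a JSON
#' sidecar `<path>.meta.json`. Reading a TIFF without a sidecar auto-names
#' pages `ch0..chN`; reading a single RGB page splits it into three
#' channels with the conventional fluorophore role mapping (red =
#' `texasred`, green = `fitc`, blue = `dapi`). Intensities are rounded to
#' integers on write, so the write/read round trip is lossless for
#' integer-valued grids.
#'
#' @param path TIFF file path.
#' @return `read_image`: a [multichannel_image()]. `write_image`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("format error: cannot read '", path, "'")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("format error reading '", path, "': ",
                           conditionMessage(e)))
  if (length(pages) == 0) stop("format error: '", path, "' has no pages")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL

  if (length(pages) == 1 && length(dim(pages[[1]])) == 3 &&
      dim(pages[[1]])[3] >= 3) {
    a <- pages[[1]]
    channels <- list(texasred = round(a[, , 1] * 65535),
                     fitc = round(a[, , 2] * 65535),
                     dapi = round(a[, , 3] * 65535))
  } else {
    channels <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      round(unclass(p) * 65535)
    })
    nm <- meta$channels %||% paste0("ch", seq_along(channels) - 1L)
    if (length(nm) != length(channels))
      nm <- paste0("ch", seq_along(channels) - 1L)
    names(channels) <- nm
  }
  channels <- lapply(channels, function(m) { attributes(m) <- list(dim = dim(m)); m })
  multichannel_image(channels,
                     pixel_size_um = meta$pixel_size_um %||% 0.1,
                     metadata = as.list(meta$metadata %||% list()))
}

#' @rdname read_image
#' @param image a [multichannel_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  pages <- lapply(image$channels, function(m)
    pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(channels = names(image$channels),
                            pixel_size_um = image$pixel_size_um,
                            metadata = image$metadata),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# ---- tabular writers (TSV with header; coordinates are 0-based row/col,
# origin top-left, as stated in each header comment) ----

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-spot ground truth as TSV
#'
#' One row per rendered spot: scene id, parent object (nucleus or
#' chromosome), channel, 0-based x (column) and y (row) coordinates, and
#' for interphase spots the shell index at generation.
#'
#' @param truth ground-truth record from a render function.
#' @param path output file.
#' @param scene_id identifier written in the first column.
#' @export
write_truth_tsv <- function(truth, path, scene_id = "scene") {
  sp <- truth$spots
  df <- data.frame(scene_id = scene_id,
                   object_id = sp$object_id %||% sp$nucleus_id,
                   channel = sp$channel,
                   x = sp$col - 1L, y = sp$row - 1L)
  if (!is.null(sp$shell_index)) df$shell_index_at_generation <- sp$shell_index
  write_tsv(df, path, "coordinates are 0-based (x = col, y = row), origin top-left")
}

#' Write per-nucleus segmentation table as TSV
#'
#' @param nuclei a `nucleus_set` from [segment_counterstain()] or
#'   [filter_nuclei()].
#' @param path output file.
#' @param scene_id identifier written in the first column.
#' @export
write_nuclei_tsv <- function(nuclei, path, scene_id = "scene") {
  ob <- nuclei$objects
  rej <- attr(nuclei, "rejected")
  df <- data.frame(scene_id = scene_id, label = ob$label,
                   area_px = ob$area_px,
                   centroid_x = ob$centroid_col - 1, centroid_y = ob$centroid_row - 1,
                   circularity = ob$circularity, kept = TRUE,
                   rejection_reason = "")
  if (!is.null(rej) && nrow(rej) > 0) {
    df <- rbind(df, data.frame(scene_id = scene_id, label = rej$label,
                               area_px = rej$area_px,
                               centroid_x = rej$centroid_col - 1,
                               centroid_y = rej$centroid_row - 1,
                               circularity = rej$circularity, kept = FALSE,
                               rejection_reason = rej$reason))
  }
  write_tsv(df, path, "coordinates are 0-based (x = col, y = row), origin top-left")
}

#' Write shell profiles as TSV
#'
#' One row per nucleus: scene id, nucleus label, probe, `shell_0..shell_{S-1}`
#' proportions, total signal and normalization mode.
#'
#' @param profiles list of [measure_profile()] results.
#' @param path output file.
#' @param scene_id identifier written in the first column.
#' @param labels optional nucleus labels (defaults to list position).
#' @export
write_profiles_tsv <- function(profiles, path, scene_id = "scene",
                               labels = seq_along(profiles)) {
  S <- profiles[[1]]$n_shells
  P <- do.call(rbind, lapply(profiles, function(p) p$proportions))
  colnames(P) <- paste0("shell_", 0:(S - 1L))
  df <- data.frame(scene_id = scene_id, nucleus_label = labels,
                   probe = vapply(profiles, function(p) p$probe_name,
                                  character(1)), P,
                   total_signal = vapply(profiles, function(p) p$total_signal,
                                         numeric(1)),
                   normalization = vapply(profiles,
                                          function(p) p$normalization,
                                          character(1)))
  write_tsv(df, path, "shell 0 is the most peripheral shell")
}

#' Write positioning test results as TSV
#'
#' @param results list of `positioning_test` objects.
#' @param path output file.
#' @export
write_results_tsv <- function(results, path) {
  if (inherits(results, "positioning_test")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(comparison = r$comparison,
               groups = paste(r$groups, collapse = "|"),
               n_shells = r$n_shells, statistic = r$statistic, df = r$df,
               p_raw = r$p_raw,
               p_adjusted = r$p_adjusted %||% NA_real_,
               pseudo_n_per_nucleus = r$pseudo_n_per_nucleus,
               warnings = paste(r$warnings, collapse = "; "))))
  write_tsv(df, path)
}

# run manifest: enough to regenerate every output (config echo + seed)
write_manifest <- function(path, config, seed, outputs) {
  jsonlite::write_json(
    list(package = "cytofish",
         version = as.character(utils::packageVersion("cytofish")),
         seed = seed, config = config, outputs = outputs,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
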