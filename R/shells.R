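#' Decompose a nucleus mask into concentric shells
#'
#' Partitions a single-nucleus binary mask into `n_shells` concentric
#' shells indexed `0` (most peripheral) to `n_shells - 1` (most central),
#' the indexing convention used for radial-position bar charts. Two
#' decompositions are supported:
#'
#' \describe{
#'   \item{`equal_area`}{pixels are ranked by their Euclidean
#'     distance-to-boundary and split into `n_shells` groups of (near)
#'     equal pixel count, i.e. shells are quantile bands of the distance
#'     transform. Ties in distance are broken by stable `(row, col)`
#'     ordering, so the decomposition is fully deterministic.}
#'   \item{`fixed_erosion`}{the distance range `(0, max]` is cut into
#'     `n_shells` bands of equal width (equal erosion depth relative to the
#'     maximal inscribed radius); shell areas then shrink toward the
#'     centre, as in classical erosion-script shell analysis.}
#' }
#'
#' @param mask binary matrix with a single connected nucleus of at least
#'   `25 * n_shells` pixels.
#' @param n_shells number of shells S (default 5).
#' @param mode `"equal_area"` (default) or `"fixed_erosion"`.
#' @return an object of class `shell_map`: list with `shell_index` (integer
#'   matrix, `NA` outside the mask, values `0..S-1`), `shell_areas_px`,
#'   `n_shells`, `mode`, `nucleus_area_px`.
#' @examples
#' m <- make_nucleus_mask(25, seed = 1)
#' sm <- compute_shells(m, 5)
#' sm$shell_areas_px          # five nearly equal areas
#' @export
compute_shells <- function(mask, n_shells = 5L,
                           mode = c("equal_area", "fixed_erosion")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask))
  if (!is_binary_mask(mask)) stop("mask must be binary")
  n_shells <- as.integer(n_shells)
  if (n_shells < 1L) stop("n_shells must be >= 1")
  area <- sum(mask != 0)
  if (area < 25L * n_shells)
    stop("degenerate input: mask has ", area, " px, need >= ", 25L * n_shells)
  if (n_components(mask) != 1L)
    stop("degenerate input: mask must be a single connected component")

  d <- boundary_distance(mask)
  idx <- which(mask != 0)
  shell <- matrix(NA_integer_, nrow(mask), ncol(mask))

  if (mode == "equal_area") {
    rr <- (idx - 1L) %% nrow(mask) + 1L
    cc <- (idx - 1L) %/% nrow(mask) + 1L
    ord <- order(d[idx], rr, cc)
    # chunk sizes differ by at most one pixel
    base <- area %/% n_shells
    sizes <- rep(base, n_shells)
    extra <- area - base * n_shells
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    shell[idx[ord]] <- rep(0:(n_shells - 1L), times = sizes)
  } else {
    w <- max(d[idx]) / n_shells
    s <- pmin(ceiling(d[idx] / w) - 1L, n_shells - 1L)
    shell[idx] <- as.integer(pmax(s, 0L))
  }

  areas <- vapply(0:(n_shells - 1L),
                  function(s) sum(shell[idx] == s), numeric(1))
  structure(list(shell_index = shell, shell_areas_px = areas,
                 n_shells = n_shells, mode = mode, nucleus_area_px = area),
            class = "shell_map")
}

#' @export
print.shell_map <- function(x, ...) {
  cat("<shell_map> ", x$n_shells, " shells (", x$mode, "), nucleus area ",
      x$nucleus_area_px, " px\n", sep = "")
  cat("  areas (0 = peripheral):", paste(x$shell_areas_px, collapse = " "), "\n")
  invisible(x)
}

#' Shell index at given pixel coordinates
#'
#' @param shells a [compute_shells()] result.
#' @param coords data.frame or matrix with 1-based `row`, `col` columns.
#' @return integer vector of 0-based shell indices (`NA` outside the mask).
#' @export
shell_at <- function(shells, coords) {
  stopifnot(inherits(shells, "shell_map"))
  coords <- as.matrix(coords[, c("row", "col"), drop = FALSE])
  shells$shell_index[cbind(coords[, 1], coords[, 2])]
}

#' Measure the per-shell proportion of FISH signal in one nucleus
#'
#' Sums probe intensity over each concentric shell of a nucleus and
#' expresses it as a proportion of the nuclear total. Optionally the modal
#' background level is subtracted first (clamped at zero), and optionally
#' the per-shell signal fraction is divided by the per-shell counterstain
#' fraction (then renormalized), for workflows that normalize probe signal
#' by DAPI content.
#'
#' @param shells a [compute_shells()] result.
#' @param signal 2D probe intensity grid, same dimensions as the mask.
#' @param counterstain optional 2D counterstain grid (required for
#'   `normalization = "counterstain_normalized"`).
#' @param normalization `"raw"` (default) or `"counterstain_normalized"`.
#' @param background_subtract subtract the modal signal level first?
#' @param probe_name label stored in the profile.
#' @return object of class `signal_profile`: `proportions` (length S, sums
#'   to 1), `shell_sums`, `total_signal`, plus bookkeeping fields. If no
#'   signal remains after subtraction the profile is flagged empty
#'   (`total_signal = 0`, proportions `NA`) and is excluded by
#'   [aggregate_profiles()].
#' @export
measure_profile <- function(shells, signal, counterstain = NULL,
                            normalization = c("raw", "counterstain_normalized"),
                            background_subtract = FALSE,
                            probe_name = "probe") {
  normalization <- match.arg(normalization)
  stopifnot(inherits(shells, "shell_map"), is.matrix(signal))
  if (!all(dim(signal) == dim(shells$shell_index)))
    stop("signal dimensions do not match the shell map")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (normalization == "counterstain_normalized") {
    if (is.null(counterstain)) stop("counterstain grid required")
    if (!all(dim(counterstain) == dim(shells$shell_index)))
      stop("counterstain dimensions do not match the shell map")
  }
  S <- shells$n_shells
  sig <- signal
  if (background_subtract) sig <- pmax(sig - modal_value(sig), 0)

  inside <- !is.na(shells$shell_index)
  sums <- vapply(0:(S - 1L), function(s)
    sum(sig[inside & shells$shell_index == s]), numeric(1))
  total <- sum(sums)

  if (total <= 0) {
    prop <- rep(NA_real_, S)
    total <- 0
  } else if (normalization == "raw") {
    prop <- sums / total
  } else {
    cs <- vapply(0:(S - 1L), function(s)
      sum(counterstain[inside & shells$shell_index == s]), numeric(1))
    if (any(cs <= 0)) stop("counterstain fraction is zero in some shell")
    ratio <- (sums / total) / (cs / sum(cs))
    prop <- ratio / sum(ratio)
  }
  structure(list(proportions = prop, shell_sums = sums, total_signal = total,
                 n_shells = S, probe_name = probe_name,
                 normalization = normalization,
                 nucleus_area_px = shells$nucleus_area_px),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, digits = 3, ...) {
  cat("<signal_profile> probe ", x$probe_name, ", ", x$normalization,
      ", total signal ", format(x$total_signal, digits = digits), "\n", sep = "")
  if (x$total_signal > 0)
    cat("  proportions (shell 0..", x$n_shells - 1L, "): ",
        paste(round(x$proportions, digits), collapse = " "), "\n", sep = "")
  else cat("  empty profile (no signal)\n")
  invisible(x)
}

#' Pool per-nucleus shell profiles into a group-level profile
#'
#' Averages the per-nucleus proportion vectors (unweighted, so each nucleus
#' counts equally regardless of its total signal) and sums raw signal per
#' shell. Empty profiles (`total_signal == 0`) are excluded from both.
#'
#' @param profiles list of [measure_profile()] results sharing S and probe.
#' @param group_name label for the pooled group (e.g. `"fused"`).
#' @return object of class `aggregate_profile` with `mean_proportions`,
#'   `summed_signal_by_shell`, `n_nuclei`.
#' @export
aggregate_profiles <- function(profiles, group_name = "group") {
  if (length(profiles) == 0) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "signal_profile")))
  S <- unique(vapply(profiles, function(p) p$n_shells, integer(1)))
  if (length(S) != 1) stop("profiles mix different shell counts")
  pr <- unique(vapply(profiles, function(p) p$probe_name, character(1)))
  if (length(pr) != 1) stop("profiles mix different probes")
  keep <- vapply(profiles, function(p) p$total_signal > 0, logical(1))
  profiles <- profiles[keep]
  if (length(profiles) == 0) stop("all profiles are empty")
  P <- do.call(rbind, lapply(profiles, function(p) p$proportions))
  sums <- colSums(do.call(rbind, lapply(profiles, function(p) p$shell_sums)))
  structure(list(group_name = group_name, n_nuclei = length(profiles),
                 mean_proportions = colMeans(P),
                 summed_signal_by_shell = sums,
                 n_shells = S, probe_name = pr),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, digits = 3, ...) {
  cat("<aggregate_profile> ", x$group_name, " (probe ", x$probe_name, "), ",
      x$n_nuclei, " nuclei\n", sep = "")
  cat("  mean proportions (shell 0..", x$n_shells - 1L, "): ",
      paste(round(x$mean_proportions, digits), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Bar plot of group-level shell profiles
#'
#' Grouped bars of mean per-shell signal proportion, shells 0 (peripheral)
#' to S-1 (central) on the x axis, one bar series per group — the standard
#' layout for radial-positioning figures.
#'
#' @param aggregates list of [aggregate_profiles()] results (or a single one).
#' @param shade_groups optional character vector of group names drawn in
#'   gray (conventionally the fused group).
#' @param ... passed to [graphics::barplot()].
#' @export
plot_shell_profiles <- function(aggregates, shade_groups = character(), ...) {
  if (inherits(aggregates, "aggregate_profile")) aggregates <- list(aggregates)
  M <- do.call(rbind, lapply(aggregates, function(a) a$mean_proportions))
  rownames(M) <- vapply(aggregates, function(a) a$group_name, character(1))
  colnames(M) <- as.character(0:(ncol(M) - 1L))
  cols <- ifelse(rownames(M) %in% shade_groups, gray(0.55), gray(0.9))
  graphics::barplot(M, beside = TRUE, col = cols, border = "black",
                    xlab = "shell (0 = peripheral)",
                    ylab = "mean proportion of signal", ...)
  graphics::legend("topleft", legend = rownames(M), fill = cols, bty = "n")
  invisible(M)
}

#' @rdname plot_shell_profiles
#' @param x an `aggregate_profile`.
#' @export
plot.aggregate_profile <- function(x, ...) plot_shell_profiles(list(x), ...)
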