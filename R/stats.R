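new_positioning_test <- function(comparison, statistic, df, p_raw,
                                 pseudo_n, groups, warnings = character(),
                                 n_shells = NA_integer_) {
  structure(list(comparison = comparison, statistic = statistic, df = df,
                 p_raw = p_raw, p_adjusted = NULL,
                 pseudo_n_per_nucleus = pseudo_n, groups = groups,
                 warnings = warnings, n_shells = n_shells),
            class = "positioning_test")
}

#' @export
print.positioning_test <- function(x, digits = 4, ...) {
  cat("<positioning_test> ", x$comparison, " [",
      paste(x$groups, collapse = " vs "), "]\n", sep = "")
  cat("  X-squared = ", format(x$statistic, digits = digits),
      ", df = ", x$df, ", p = ", format.pval(x$p_raw, digits = digits),
      if (!is.null(x$p_adjusted))
        paste0(", p (Bonferroni) = ", format.pval(x$p_adjusted,
                                                  digits = digits)),
      "\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings,
                                                   collapse = "; "), "\n")
  invisible(x)
}

#' Chi-square test of a shell profile against the random pattern
#'
#' Tests whether a pooled radial signal distribution differs from the
#' random (area-proportional) expectation. Mean per-shell proportions are
#' converted to pseudo-counts — `pseudo_n_per_nucleus` counting units per
#' nucleus, so the total count reflects the number of nuclei rather than
#' the pixel count, which would inflate with magnification — and compared
#' to expected counts `shell_areas_fraction * total` with the usual
#' goodness-of-fit statistic `sum((O - E)^2 / E)` on `S - 1` degrees of
#' freedom. The statistic is linear in `pseudo_n_per_nucleus`; choose it
#' to match the granularity of the per-nucleus signal (see the package
#' vignette).
#'
#' @param agg an [aggregate_profiles()] result.
#' @param shell_areas_fraction expected per-shell fractions under the
#'   random pattern; defaults to equal fractions `1/S` (exact for
#'   equal-area shells).
#' @param pseudo_n_per_nucleus counting units per nucleus (default 100).
#' @return a `positioning_test` (fields `statistic`, `df`, `p_raw`, ...).
#' @examples
#' prof <- list(structure(list(proportions = rep(0.2, 5),
#'   shell_sums = rep(20, 5), total_signal = 100, n_shells = 5L,
#'   probe_name = "p", normalization = "raw", nucleus_area_px = 5000),
#'   class = "signal_profile"))
#' chisq_vs_random(aggregate_profiles(prof))  # statistic 0, p = 1
#' @export
chisq_vs_random <- function(agg, shell_areas_fraction = NULL,
                            pseudo_n_per_nucleus = 100L) {
  stopifnot(inherits(agg, "aggregate_profile"), agg$n_nuclei >= 1,
            pseudo_n_per_nucleus >= 1)
  S <- agg$n_shells
  if (is.null(shell_areas_fraction)) shell_areas_fraction <- rep(1 / S, S)
  if (length(shell_areas_fraction) != S)
    stop("expected fractions must have length ", S)
  if (abs(sum(shell_areas_fraction) - 1) > 1e-6)
    stop("expected fractions must sum to 1")
  if (any(shell_areas_fraction <= 0))
    stop("expected count of zero in some shell")
  total <- agg$n_nuclei * pseudo_n_per_nucleus
  O <- agg$mean_proportions * total
  E <- shell_areas_fraction * total
  warn <- character()
  if (any(E < 5)) warn <- "expected count < 5 in some shell"
  stat <- sum((O - E)^2 / E)
  res <- new_positioning_test("vs_random", stat, S - 1L,
                              pchisq(stat, S - 1L, lower.tail = FALSE),
                              pseudo_n_per_nucleus,
                              c(agg$group_name, "random"), warn, S)
  res
}

#' Chi-square homogeneity test between two shell profiles
#'
#' Compares the radial distribution of two pooled groups (canonically the
#' species where the probed microchromosome is fused to a macrochromosome
#' versus the unfused species) with a standard 2 x S homogeneity
#' chi-square on pseudo-counts (`mean_proportions * n_nuclei *
#' pseudo_n_per_nucleus` per group). Shells with zero combined count are
#' pooled with their inward neighbour before testing (recorded in the
#' result's warnings).
#'
#' @param agg_a,agg_b [aggregate_profiles()] results with equal S.
#' @param pseudo_n_per_nucleus counting units per nucleus (default 100).
#' @return a `positioning_test` with `df = S' - 1` (after any pooling).
#' @export
chisq_groups <- function(agg_a, agg_b, pseudo_n_per_nucleus = 100L) {
  stopifnot(inherits(agg_a, "aggregate_profile"),
            inherits(agg_b, "aggregate_profile"))
  if (agg_a$n_shells != agg_b$n_shells)
    stop("groups have different shell counts")
  S <- agg_a$n_shells
  Oa <- agg_a$mean_proportions * agg_a$n_nuclei * pseudo_n_per_nucleus
  Ob <- agg_b$mean_proportions * agg_b$n_nuclei * pseudo_n_per_nucleus
  warn <- character()
  # pool empty shells inward (toward higher index; the innermost pools
  # outward)
  s <- S
  while (s >= 1) {
    if (Oa[s] + Ob[s] == 0 && length(Oa) > 1) {
      nb <- if (s < length(Oa)) s + 1L else s - 1L
      Oa[nb] <- Oa[nb] + Oa[s]; Ob[nb] <- Ob[nb] + Ob[s]
      Oa <- Oa[-s]; Ob <- Ob[-s]
      warn <- c(warn, paste0("shell ", s - 1L,
                             " had zero combined count; pooled"))
    }
    s <- s - 1L
  }
  Sp <- length(Oa)
  tab <- rbind(Oa, Ob)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- Sp - 1L
  new_positioning_test("between_groups", stat, df,
                       pchisq(stat, df, lower.tail = FALSE),
                       pseudo_n_per_nucleus,
                       c(agg_a$group_name, agg_b$group_name), warn, S)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests in the family and clamps
#' at 1 (equivalent to dividing the significance level); order preserved.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' adjust_bonferroni(c(0.01, 0.5))  # 0.02, 1.0
#' @export
adjust_bonferroni <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "bonferroni")
}

#' Directional summary of a radial distribution
#'
#' Classifies a pooled shell profile as `peripheral`, `central` or
#' `intermediate` from its signal-weighted mean shell index relative to
#' the mid-shell `(S - 1) / 2`, with a dead-band of `margin` shells.
#'
#' @param agg an [aggregate_profiles()] result.
#' @param margin dead-band half-width in shell units (default 0.25).
#' @return `"peripheral"`, `"central"` or `"intermediate"`.
#' @export
position_summary <- function(agg, margin = 0.25) {
  stopifnot(inherits(agg, "aggregate_profile"))
  S <- agg$n_shells
  mean_shell <- sum((0:(S - 1)) * agg$mean_proportions)
  mid <- (S - 1) / 2
  if (mean_shell > mid + margin) "central"
  else if (mean_shell < mid - margin) "peripheral"
  else "intermediate"
}
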