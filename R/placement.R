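#' Radial placement models for probe signal
#'
#' Describes how probe spots are placed radially within a nucleus mask.
#' Radial position is defined shape-independently through the Euclidean
#' distance-to-boundary transform: a spot's radial coordinate is the
#' within-nucleus quantile of its boundary distance (0 = at the periphery,
#' 1 = the most internal pixel).
#'
#' \describe{
#'   \item{`uniform_area`}{every foreground pixel equally likely — the
#'     "random pattern" null against which radial distributions are tested.}
#'   \item{`shell_weights`}{a vector of S non-negative weights summing to
#'     1; a spot falls in equal-area shell s with probability `weights[s]`
#'     (shell 0 peripheral), uniformly within the shell.}
#'   \item{`beta_radial`}{the radial quantile is drawn from a Beta(a, b)
#'     distribution; e.g. `a > b` biases spots toward the centre.}
#' }
#'
#' @param kind one of `"uniform_area"`, `"shell_weights"`, `"beta_radial"`.
#' @param shell_weights weights vector (only for `kind = "shell_weights"`).
#' @param beta_params numeric `c(a, b)` (only for `kind = "beta_radial"`).
#' @return object of class `radial_placement`.
#' @examples
#' radial_placement("shell_weights", shell_weights = c(.1, .1, .2, .3, .3))
#' @export
radial_placement <- function(kind = c("uniform_area", "shell_weights",
                                      "beta_radial"),
                             shell_weights = NULL, beta_params = NULL) {
  kind <- match.arg(kind)
  if (kind == "shell_weights") {
    if (is.null(shell_weights) || !is.null(beta_params))
      stop("shell_weights (and only shell_weights) must be set")
    if (any(shell_weights < 0) || abs(sum(shell_weights) - 1) > 1e-9)
      stop("shell weights must be non-negative and sum to 1")
  } else if (kind == "beta_radial") {
    if (is.null(beta_params) || !is.null(shell_weights))
      stop("beta_params (and only beta_params) must be set")
    if (length(beta_params) != 2 || any(beta_params <= 0))
      stop("beta_params must be two positive numbers (a, b)")
  } else {
    if (!is.null(shell_weights) || !is.null(beta_params))
      stop("uniform_area takes no extra parameters")
  }
  structure(list(kind = kind, shell_weights = shell_weights,
                 beta_params = beta_params), class = "radial_placement")
}

#' @export
print.radial_placement <- function(x, ...) {
  cat("<radial_placement>", x$kind)
  if (x$kind == "shell_weights")
    cat(" (", paste(x$shell_weights, collapse = ", "), ")", sep = "")
  if (x$kind == "beta_radial")
    cat(" (a=", x$beta_params[1], ", b=", x$beta_params[2], ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Sample spot positions inside a nucleus mask under a placement model
#'
#' @param mask binary nucleus mask with at least 100 foreground pixels.
#' @param model a [radial_placement()] object.
#' @param n number of positions to draw.
#' @param seed optional RNG seed.
#' @param shells optional precomputed equal-area [compute_shells()] map for
#'   `shell_weights` models (must match `length(shell_weights)`); computed
#'   on the fly when missing.
#' @return data.frame with 1-based `row`, `col` pixel coordinates, one row
#'   per sampled position; all positions lie inside the mask.
#' @export
sample_radial_positions <- function(mask, model, n, seed = NULL,
                                    shells = NULL) {
  stopifnot(inherits(model, "radial_placement"), n >= 1)
  if (!is.matrix(mask) || !is_binary_mask(mask)) stop("mask must be binary")
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("degenerate input: empty mask")
  if (length(idx) < 100) stop("degenerate input: mask has < 100 pixels")
  nr <- nrow(mask)

  with_seed(seed, {
    picked <- switch(model$kind,
      uniform_area = idx[sample.int(length(idx), n, replace = TRUE)],
      shell_weights = {
        S <- length(model$shell_weights)
        if (is.null(shells)) shells <- compute_shells(mask, S, "equal_area")
        if (shells$n_shells != S)
          stop("parameter error: shell map has ", shells$n_shells,
               " shells but weights have length ", S)
        si <- shells$shell_index[idx]
        draw <- sample.int(S, n, replace = TRUE,
                           prob = model$shell_weights) - 1L
        by_shell <- split(idx, si)
        vapply(draw, function(s) {
          px <- by_shell[[as.character(s)]]
          px[sample.int(length(px), 1L)]
        }, numeric(1))
      },
      beta_radial = {
        d <- boundary_distance(mask)
        rr <- (idx - 1L) %% nr + 1L
        cc <- (idx - 1L) %/% nr + 1L
        sorted <- idx[order(d[idx], rr, cc)]
        q <- rbeta(n, model$beta_params[1], model$beta_params[2])
        rank <- pmin(length(sorted), floor(q * length(sorted)) + 1L)
        sorted[rank]
      })
    data.frame(row = (picked - 1L) %% nr + 1L,
               col = (picked - 1L) %/% nr + 1L)
  })
}

#' Simulate per-nucleus shell profiles under a placement model
#'
#' Draws `spots_per_nucleus` unit-intensity spots per nucleus from the
#' placement model and converts the shell indices of the sampled positions
#' directly into per-nucleus signal profiles — the noise-free,
#' measurement-exact counterpart of rendering an image and measuring it.
#' Used for statistical calibration and parameter-recovery studies where
#' thousands of nuclei are needed.
#'
#' @param mask binary nucleus mask (a single representative nucleus; the
#'   placement model is defined relative to the mask's own geometry).
#' @param placement a [radial_placement()] model.
#' @param n_nuclei number of nuclei to simulate.
#' @param spots_per_nucleus unit spots (counting units) per nucleus.
#' @param n_shells number of equal-area shells (default 5).
#' @param seed RNG seed.
#' @return list of `signal_profile` objects, one per nucleus.
#' @export
simulate_shell_profiles <- function(mask, placement, n_nuclei,
                                    spots_per_nucleus, n_shells = 5L,
                                    seed = NULL) {
  shells <- compute_shells(mask, n_shells, "equal_area")
  ws <- if (placement$kind == "shell_weights")
    compute_shells(mask, length(placement$shell_weights), "equal_area")
  else NULL
  with_seed(seed, {
    # one batched draw for all nuclei, split afterwards
    pos <- sample_radial_positions(mask, placement,
                                   n_nuclei * spots_per_nucleus,
                                   seed = NULL, shells = ws)
    si <- shell_at(shells, pos)
    nucleus <- rep(seq_len(n_nuclei), each = spots_per_nucleus)
    counts <- matrix(tabulate(si + 1L + n_shells * (nucleus - 1L),
                              nbins = n_shells * n_nuclei),
                     nrow = n_shells)
    lapply(seq_len(n_nuclei), function(i)
      structure(list(proportions = counts[, i] / spots_per_nucleus,
                     shell_sums = as.numeric(counts[, i]),
                     total_signal = spots_per_nucleus,
                     n_shells = as.integer(n_shells), probe_name = "sim",
                     normalization = "raw",
                     nucleus_area_px = shells$nucleus_area_px),
                class = "signal_profile"))
  })
}
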