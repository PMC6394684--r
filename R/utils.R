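# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All exported stochastic operations take an explicit seed and
# route through this; there is no hidden global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a stream-specific child seed so sub-operations don't share streams
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483587L
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1, TRUE, FALSE))
}

as_mask <- function(m) {
  storage.mode(m) <- "double"
  m
}

# number of 4-connected components of a binary mask
n_components <- function(mask) {
  if (sum(mask) == 0) return(0L)
  as.integer(max(EBImage::bwlabel(as_mask(mask))))
}

# most frequent value of a grid, used as the modal background estimate;
# continuous inputs are binned at integer resolution
modal_value <- function(x) {
  v <- round(as.numeric(x))
  tab <- tabulate(v - min(v) + 1L)
  min(v) + which.max(tab) - 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
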