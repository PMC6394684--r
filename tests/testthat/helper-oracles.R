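# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# exact Euclidean distance from every foreground pixel to the nearest
# background pixel (image border counts as background), by direct search
# over background pixels adjacent to the mask plus the border ring
brute_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(pad == 0, arr.ind = TRUE)
  fg <- which(pad == 1, arr.ind = TRUE)
  # restrict background to pixels bordering the object's bounding box
  keep <- bg[, 1] >= min(fg[, 1]) - 1 & bg[, 1] <= max(fg[, 1]) + 1 &
          bg[, 2] >= min(fg[, 2]) - 1 & bg[, 2] <= max(fg[, 2]) + 1
  bg <- bg[keep, , drop = FALSE]
  d <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nrow(fg))) {
    d[fg[i, 1] - 1, fg[i, 2] - 1] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  d
}

# equal-area shells by explicit sort of the brute-force distances, stable
# (row, col) tie-break; returns an integer matrix 0..S-1 / NA
brute_shells <- function(mask, S) {
  d <- brute_distance(mask)
  idx <- which(mask == 1)
  rr <- (idx - 1) %% nrow(mask) + 1
  cc <- (idx - 1) %/% nrow(mask) + 1
  ord <- order(d[idx], rr, cc)
  n <- length(idx)
  sizes <- rep(n %/% S, S)
  if (n %% S > 0) sizes[seq_len(n %% S)] <- sizes[seq_len(n %% S)] + 1
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  out[idx[ord]] <- rep(0:(S - 1), times = sizes)
  out
}

disc_mask <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- matrix(0L, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 1L
  m
}

# rotate a matrix by 90 degrees (counter-clockwise)
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
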