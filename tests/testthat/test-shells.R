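test_that("equal-area shells of a disc match the analytic annulus radii", {
  r <- 100
  m <- disc_mask(r)
  sm <- compute_shells(m, 5)
  # shell s spans the annulus between r*sqrt(1 - (s+1)/5) and
  # r*sqrt(1 - s/5) from the centre; check the observed outer radius of
  # each shell (max distance from centre among its pixels)
  ctr <- which(cytofish:::boundary_distance(m) == max(cytofish:::boundary_distance(m)),
               arr.ind = TRUE)[1, ]
  for (s in 0:4) {
    px <- which(sm$shell_index == s, arr.ind = TRUE)
    r_out <- max(sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2))
    expect_equal(r_out, r * sqrt(1 - s / 5), tolerance = 0.03)
  }
  expect_true(all(abs(sm$shell_areas_px - sum(m) / 5) <= 1))
})

test_that("a single shell equals the whole mask", {
  m <- make_nucleus_mask(25, seed = 5)
  sm <- compute_shells(m, 1)
  expect_identical(sm$shell_areas_px, sum(m) + 0)
  expect_true(all(sm$shell_index[m == 1] == 0L))
  expect_true(all(is.na(sm$shell_index[m == 0])))
})

test_that("shell decomposition is an exact partition with near-equal areas", {
  for (seed in 1:5) {
    m <- make_nucleus_mask(runif(1, 35, 50), runif(1, 0, 0.5), seed = seed)
    sm <- compute_shells(m, 5)
    inside <- !is.na(sm$shell_index)
    expect_identical(unname(inside), m == 1)           # exact partition
    expect_identical(sum(sm$shell_areas_px), sum(m) + 0)
    expect_true(all(abs(sm$shell_areas_px - sum(m) / 5) <=
                      0.02 * sum(m) / 5))
  }
})

test_that("equal-area shells agree with the brute-force quantile oracle", {
  for (seed in c(11, 12)) {
    m <- make_nucleus_mask(30, eccentricity = 0.3, seed = seed)
    sm <- compute_shells(m, 5)
    oracle <- brute_shells(m, 5)
    idx <- which(m == 1)
    agree <- mean(sm$shell_index[idx] == oracle[idx])
    expect_gte(agree, 0.99)
  }
})

test_that("fixed-erosion shells use equal-width distance bands", {
  m <- disc_mask(60)
  sm <- compute_shells(m, 5, mode = "fixed_erosion")
  d <- cytofish:::boundary_distance(m)
  w <- max(d[m == 1]) / 5
  idx <- which(m == 1)
  expect_true(all(sm$shell_index[idx] ==
                    pmin(pmax(ceiling(d[idx] / w) - 1, 0), 4)))
  # areas shrink toward the centre for a disc
  expect_true(all(diff(sm$shell_areas_px) < 0))
})

test_that("degenerate masks are rejected", {
  expect_error(compute_shells(matrix(0, 30, 30), 5), "degenerate")
  small <- matrix(0L, 30, 30); small[14:16, 14:16] <- 1L
  expect_error(compute_shells(small, 5), "degenerate")
  two <- matrix(0L, 60, 60)
  two[5:25, 5:25] <- 1L; two[35:55, 35:55] <- 1L
  expect_error(compute_shells(two, 5), "connected")
})

test_that("profile of a single bright pixel at the centre is all-central", {
  m <- disc_mask(40)
  sm <- compute_shells(m, 5)
  d <- cytofish:::boundary_distance(m)
  sig <- matrix(0, nrow(m), ncol(m))
  sig[which.max(d)] <- 1
  p <- measure_profile(sm, sig)
  expect_equal(p$proportions, c(0, 0, 0, 0, 1))
})

test_that("uniform signal over equal-area shells gives flat proportions", {
  m <- make_nucleus_mask(40, 0.2, seed = 9)
  sm <- compute_shells(m, 5)
  sig <- matrix(0, nrow(m), ncol(m)); sig[m == 1] <- 7
  p <- measure_profile(sm, sig)
  expect_true(all(abs(p$proportions - 0.2) < 0.005))
})

test_that("measured proportions recover generating shell weights", {
  m <- make_nucleus_mask(42, 0.3, seed = 10)
  sm <- compute_shells(m, 5)
  w <- c(0.1, 0.1, 0.2, 0.3, 0.3)
  pos <- sample_radial_positions(m, radial_placement("shell_weights",
                                                     shell_weights = w),
                                 1e4, seed = 4)
  sig <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(pos)))
    sig[pos$row[i], pos$col[i]] <- sig[pos$row[i], pos$col[i]] + 1
  p <- measure_profile(sm, sig)
  expect_true(max(abs(p$proportions - w)) < 0.02)
})

test_that("empty and background-subtracted profiles behave as specified", {
  m <- make_nucleus_mask(30, seed = 11)
  sm <- compute_shells(m, 5)
  p0 <- measure_profile(sm, matrix(0, nrow(m), ncol(m)))
  expect_identical(p0$total_signal, 0)
  expect_true(all(is.na(p0$proportions)))
  # constant background + one spot: subtraction leaves only the spot
  sig <- matrix(10, nrow(m), ncol(m))
  d <- cytofish:::boundary_distance(m)
  sig[which.max(d)] <- 30
  p <- measure_profile(sm, sig, background_subtract = TRUE)
  expect_equal(p$proportions, c(0, 0, 0, 0, 1))
  expect_equal(p$total_signal, 20)
})

test_that("counterstain normalization with uniform counterstain matches raw", {
  m <- make_nucleus_mask(35, seed = 12)
  sm <- compute_shells(m, 5)
  sig <- matrix(0, nrow(m), ncol(m))
  sig[m == 1] <- runif(sum(m))
  cs <- matrix(0, nrow(m), ncol(m)); cs[m == 1] <- 5
  praw <- measure_profile(sm, sig)
  pnorm <- measure_profile(sm, sig, counterstain = cs,
                           normalization = "counterstain_normalized")
  # equal up to the +/-1 px rounding of equal-area shell sizes
  expect_equal(pnorm$proportions, praw$proportions, tolerance = 1e-3)
})

test_that("rotating mask and signal by 90 degrees leaves profiles unchanged", {
  m <- make_nucleus_mask(36, eccentricity = 0.4, seed = 13)
  # uniform signal: exact invariance in equal-area mode (tied pixels carry
  # equal weight, so quantile tie-breaking cannot move signal)
  sig <- matrix(0, nrow(m), ncol(m)); sig[m == 1] <- 3
  p1 <- measure_profile(compute_shells(m, 5), sig)
  p2 <- measure_profile(compute_shells(rot90(m), 5), rot90(sig))
  expect_identical(p1$proportions, p2$proportions)
  # arbitrary signal: exact invariance in fixed_erosion mode (shell index
  # is a pure function of the rotation-invariant distance transform)
  sig2 <- matrix(0, nrow(m), ncol(m))
  sig2[m == 1] <- seq_len(sum(m)) %% 17
  q1 <- measure_profile(compute_shells(m, 5, "fixed_erosion"), sig2)
  q2 <- measure_profile(compute_shells(rot90(m), 5, "fixed_erosion"),
                        rot90(sig2))
  expect_identical(q1$proportions, q2$proportions)
})

test_that("aggregation averages proportions and counts non-empty nuclei", {
  mk <- function(p, total = 1) structure(
    list(proportions = p, shell_sums = p * total, total_signal = total,
         n_shells = 5L, probe_name = "p", normalization = "raw",
         nucleus_area_px = 1000), class = "signal_profile")
  a <- aggregate_profiles(list(mk(c(1, 0, 0, 0, 0)),
                               mk(c(0, 0, 0, 0, 1))), "g")
  expect_equal(a$mean_proportions, c(0.5, 0, 0, 0, 0.5))
  expect_identical(a$n_nuclei, 2L)
  b <- aggregate_profiles(rep(list(mk(c(.2, .2, .2, .2, .2))), 75), "g")
  expect_identical(b$n_nuclei, 75L)
  expect_equal(b$mean_proportions, rep(0.2, 5))
  # empty profiles are dropped
  empty <- mk(rep(NA_real_, 5), total = 0)
  d <- aggregate_profiles(list(mk(c(1, 0, 0, 0, 0)), empty), "g")
  expect_identical(d$n_nuclei, 1L)
  expect_error(aggregate_profiles(list()), "empty")
  p3 <- structure(list(proportions = rep(1 / 3, 3), shell_sums = rep(1, 3),
                       total_signal = 3, n_shells = 3L, probe_name = "p",
                       normalization = "raw", nucleus_area_px = 10),
                  class = "signal_profile")
  expect_error(aggregate_profiles(list(mk(rep(.2, 5)), p3)), "shell counts")
})

test_that("pooled uniform-placement nuclei are flat to within 0.03", {
  m <- make_nucleus_mask(40, 0.2, seed = 14)
  profs <- simulate_shell_profiles(m, radial_placement("uniform_area"),
                                   100, 100, seed = 21)
  agg <- aggregate_profiles(profs)
  expect_true(max(abs(agg$mean_proportions - 0.2)) < 0.03)
})
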