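mkprof <- function(p, total = 100) structure(
  list(proportions = p, shell_sums = p * total, total_signal = total,
       n_shells = length(p), probe_name = "p", normalization = "raw",
       nucleus_area_px = 1000), class = "signal_profile")

test_that("chi-square vs random: identity and closed-form cases", {
  flat <- aggregate_profiles(list(mkprof(rep(0.2, 5))), "g")
  r0 <- chisq_vs_random(flat, rep(0.2, 5), pseudo_n_per_nucleus = 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  expect_identical(r0$df, 4L)
  # all signal in the outermost shell, total count 100:
  # (80^2 + 4*20^2) / 20 = 400
  one <- aggregate_profiles(list(mkprof(c(1, 0, 0, 0, 0))), "g")
  r1 <- chisq_vs_random(one, rep(0.2, 5), pseudo_n_per_nucleus = 100)
  expect_equal(r1$statistic, 400)
  expect_identical(r1$df, 4L)
})

test_that("chi-square vs random agrees with the stats::chisq.test oracle", {
  p <- c(0.27, 0.18, 0.22, 0.13, 0.20)
  agg <- aggregate_profiles(list(mkprof(p)), "g")
  mine <- chisq_vs_random(agg, rep(0.2, 5), pseudo_n_per_nucleus = 100)
  oracle <- suppressWarnings(chisq.test(p * 100, p = rep(0.2, 5)))
  expect_equal(mine$statistic, unname(oracle$statistic))
  expect_equal(mine$p_raw, oracle$p.value)
})

test_that("group test: identity gives zero, and matches chisq.test", {
  a <- aggregate_profiles(list(mkprof(c(.1, .2, .3, .2, .2))), "a")
  r <- chisq_groups(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  b <- aggregate_profiles(list(mkprof(c(.3, .3, .2, .1, .1))), "b")
  mine <- chisq_groups(a, b, pseudo_n_per_nucleus = 100)
  tab <- rbind(a$mean_proportions * 100, b$mean_proportions * 100)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(mine$statistic, unname(oracle$statistic))
  expect_equal(mine$p_raw, oracle$p.value)
  expect_identical(mine$df, 4L)
})

test_that("empty shells are pooled inward before the group test", {
  a <- aggregate_profiles(list(mkprof(c(0, .2, .3, .3, .2))), "a")
  b <- aggregate_profiles(list(mkprof(c(0, .3, .3, .2, .2))), "b")
  r <- chisq_groups(a, b)
  expect_identical(r$df, 3L)
  expect_match(r$warnings, "pooled")
})

test_that("statistic is linear in pseudo-count and p decreases with it", {
  agg <- aggregate_profiles(list(mkprof(c(.25, .25, .2, .15, .15))), "g")
  r100 <- chisq_vs_random(agg, rep(.2, 5), 100)
  r200 <- chisq_vs_random(agg, rep(.2, 5), 200)
  expect_equal(r200$statistic, 2 * r100$statistic)
  expect_lt(r200$p_raw, r100$p_raw)
})

test_that("Bonferroni adjustment is multiply-and-clamp", {
  expect_equal(adjust_bonferroni(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(adjust_bonferroni(0.3), 0.3)
  expect_equal(adjust_bonferroni(rep(0.004, 10)), rep(0.04, 10))
  expect_identical(adjust_bonferroni(numeric(0)), numeric(0))
  expect_error(adjust_bonferroni(c(0.5, 1.2)))
})

test_that("positional summary labels extreme and flat profiles", {
  central <- aggregate_profiles(list(mkprof(c(0, 0, 0, 0, 1))), "g")
  peripheral <- aggregate_profiles(list(mkprof(c(1, 0, 0, 0, 0))), "g")
  flat <- aggregate_profiles(list(mkprof(rep(.2, 5))), "g")
  expect_identical(position_summary(central), "central")
  expect_identical(position_summary(peripheral), "peripheral")
  expect_identical(position_summary(flat), "intermediate")
})

test_that("type-I error of both tests is near nominal (quick check)", {
  m <- make_nucleus_mask(40, 0.3, seed = 2)
  sm <- compute_shells(m, 5)
  frac <- sm$shell_areas_px / sum(sm$shell_areas_px)
  R <- 200
  rej1 <- rej2 <- 0
  for (r in seq_len(R)) {
    p1 <- simulate_shell_profiles(m, radial_placement("uniform_area"),
                                  75, 100, seed = 3000 + 3 * r)
    a1 <- aggregate_profiles(p1, "a")
    if (chisq_vs_random(a1, frac, 100)$p_raw < 0.05) rej1 <- rej1 + 1
    p2 <- simulate_shell_profiles(m, radial_placement("uniform_area"),
                                  75, 100, seed = 3001 + 3 * r)
    a2 <- aggregate_profiles(p2, "b")
    if (chisq_groups(a1, a2, 100)$p_raw < 0.05) rej2 <- rej2 + 1
  }
  expect_gt(rej1 / R, 0.015); expect_lt(rej1 / R, 0.10)
  expect_gt(rej2 / R, 0.015); expect_lt(rej2 / R, 0.10)
})
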