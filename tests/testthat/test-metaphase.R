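panel <- build_species_panel()

test_that("the default panel encodes the published species configurations", {
  expect_identical(length(panel), 22L)
  expect_identical(panel[["Peregrine falcon"]]$diploid_number, 50L)
  expect_identical(panel[["Budgerigar"]]$diploid_number, 62L)
  expect_identical(panel[["Eurasian woodcock"]]$diploid_number, 96L)
  # GGA15, 18, 19 share one chromosome type in all three falcons
  for (sp in c("Peregrine falcon", "Saker falcon", "Gyrfalcon")) {
    km <- panel[[sp]]
    t15 <- cytofish:::type_of_label(km, "GGA15")
    expect_identical(t15, cytofish:::type_of_label(km, "GGA18"))
    expect_identical(t15, cytofish:::type_of_label(km, "GGA19"))
    expect_true("GGA4" %in% km$chromosomes$content[[t15]])
    t23 <- cytofish:::type_of_label(km, "GGA23")
    expect_identical(t23, cytofish:::type_of_label(km, "GGA28"))
    expect_true("GGA2" %in% km$chromosomes$content[[t23]])
  }
  # ostrich: every panel micro on its own micro-class chromosome
  ko <- panel[["Common ostrich"]]
  for (lb in micro_panel_labels()) {
    ti <- cytofish:::type_of_label(ko, lb)
    expect_identical(ko$chromosomes$content[[ti]], lb)
    expect_identical(ko$chromosomes$class[ti], "micro")
  }
  # each karyotype renders exactly 2n chromosome objects
  for (km in panel)
    expect_identical(nrow(km$chromosomes) * 2L, km$diploid_number)
  expect_error(karyotype_model("x", 5,
                               panel[["Common ostrich"]]$chromosomes),
               "even")
})

test_that("metaphase rendering is deterministic and counts chromosomes", {
  km <- panel[["Chinese quail"]]
  sc1 <- render_metaphase_scene(km, c("GGA24", "GGA24"), seed = 3,
                                noise = 0)
  sc2 <- render_metaphase_scene(km, c("GGA24", "GGA24"), seed = 3,
                                noise = 0)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$truth, sc2$truth)
  cs <- segment_chromosomes(sc1$image$channels$dapi)
  expect_identical(nrow(cs$objects), 78L)
})

test_that("end probes of an intact micro land on the same two small objects", {
  km <- panel[["Chinese quail"]]
  sc <- render_metaphase_scene(km, c("GGA24", "GGA24"), seed = 3,
                               noise = 0)
  cs <- segment_chromosomes(sc$image$channels$dapi)
  sa <- detect_spots(sc$image$channels$fitc, cs, min_intensity = 1000)
  sb <- detect_spots(sc$image$channels$texasred, cs, min_intensity = 1000)
  expect_identical(nrow(sa), 2L)
  expect_identical(nrow(sb), 2L)
  expect_true(all(sa$assigned) && all(sb$assigned))
  expect_setequal(sa$label, sb$label)
  expect_identical(call_pair(sa, sb), "same")
  # carriers are micro-sized objects
  med_area <- median(cs$objects$area_px)
  expect_true(all(cs$objects$area_px[sa$label] < med_area))
})

test_that("a fused micro's probe lands on macro-sized chromosomes in falcon", {
  km <- panel[["Saker falcon"]]
  sc <- render_metaphase_scene(km, c("GGA18", "GGA24"), seed = 4,
                               noise = 0)
  cs <- segment_chromosomes(sc$image$channels$dapi)
  s18 <- detect_spots(sc$image$channels$fitc, cs, min_intensity = 1000)
  s24 <- detect_spots(sc$image$channels$texasred, cs, min_intensity = 1000)
  expect_identical(nrow(s18), 2L)
  big <- quantile(cs$objects$area_px, 0.75)
  expect_true(all(cs$objects$area_px[s18$label] > big))
  expect_identical(call_pair(s18, s24), "different")
})

test_that("probe failures yield zero spots in both channels", {
  kz <- panel[["Zebra finch"]]
  sc <- render_metaphase_scene(kz, c("GGA25", "GGA25"), seed = 5,
                               noise = 0)
  expect_identical(sum(sc$image$channels$fitc), 0)
  expect_identical(sum(sc$image$channels$texasred), 0)
  cs <- segment_chromosomes(sc$image$channels$dapi)
  s <- detect_spots(sc$image$channels$fitc, cs, min_intensity = 1000)
  expect_identical(nrow(s), 0L)
  expect_identical(call_pair(s, s), "no_call")
  expect_error(render_metaphase_scene(kz, c("GGA99", "GGA24"), seed = 1),
               "configuration error")
})

test_that("non-maximum suppression keeps the brighter of two close spots", {
  ch <- matrix(0, 40, 40)
  ch <- cytofish:::add_spot(ch, 20, 20, 1, 100)
  ch <- cytofish:::add_spot(ch, 20, 23, 1, 80)    # 3 px away, dimmer
  s5 <- detect_spots(ch, min_intensity = 20, min_separation_px = 5)
  expect_identical(nrow(s5), 1L)
  expect_identical(c(s5$row, s5$col), c(20L, 20L))
  s2 <- detect_spots(ch, min_intensity = 20, min_separation_px = 2)
  expect_identical(nrow(s2), 2L)
})

test_that("overlapping rods merge into one flagged area outlier", {
  img <- matrix(0, 120, 160)
  # six parallel rods plus one crossing pair
  for (ctr in seq(15, 65, by = 10)) img[ctr + 0:3, 20:60] <- 8000
  img[90 + 0:3, 40:90] <- 8000
  img[70:110, 62 + 0:3] <- 8000
  cs <- segment_chromosomes(img, smoothing_sigma = 0)
  expect_identical(nrow(cs$objects), 7L)
  expect_identical(sum(cs$objects$area_outlier), 1L)
  expect_identical(which(cs$objects$area_outlier),
                   which.max(cs$objects$area_px))
  empty <- segment_chromosomes(matrix(0, 30, 30))
  expect_identical(nrow(empty$objects), 0L)
})
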