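test_that("pair calling follows the homolog-matching rules", {
  sp <- function(labels) data.frame(label = labels)
  expect_identical(call_pair(sp(c(3, 7)), sp(c(3, 7))), "same")
  expect_identical(call_pair(sp(c(3, 7)), sp(c(10, 22))), "different")
  expect_identical(call_pair(sp(c(3, 7)), sp(integer())), "no_call")
  expect_identical(call_pair(sp(c(3, 7)), sp(c(3, 10))), "no_call")
  expect_identical(call_pair(sp(c(3, 7, 9)), sp(c(10, 22))), "no_call")
  expect_identical(call_pair(sp(3), sp(3)), "same")     # merged homologs
  expect_identical(call_pair(sp(3), sp(c(3, 7))), "same")  # one dropout
  expect_identical(call_pair(sp(0), sp(c(3, 7))), "no_call")  # unassigned
})

test_that("call aggregation applies the informativeness and majority rules", {
  expect_identical(aggregate_calls(rep("same", 10))$verdict, "same")
  expect_identical(aggregate_calls(c(rep("same", 4), rep("no_call", 6)),
                                   min_informative = 5)$verdict, "no_data")
  expect_identical(aggregate_calls(c(rep("same", 8), rep("different", 2)),
                                   majority = 0.8)$verdict, "same")
  expect_identical(aggregate_calls(c(rep("same", 7), rep("different", 3)),
                                   majority = 0.8)$verdict, "no_data")
  expect_identical(aggregate_calls(character())$verdict, "no_data")
  fc <- aggregate_calls(c("same", "different", "no_call"))
  expect_identical(fc$n_same + fc$n_different + fc$n_no_call, fc$n_spreads)
})

test_that("rearrangement maps recover the generating falcon configuration", {
  panel <- build_species_panel()
  km <- panel[["Peregrine falcon"]]
  sim <- simulate_species_calls(km, n_spreads = 10, drop_rate = 0,
                                misassign_rate = 0, seed = 2)
  map <- build_rearrangement_map(km$species, sim$pairwise,
                                 sim$carrier_class)
  grp <- map$fusion_groups[[which(vapply(map$fusion_groups,
                                         function(g) "GGA18" %in% g,
                                         logical(1)))]]
  expect_setequal(grp, c("GGA4", "GGA15", "GGA18", "GGA19"))
  grp2 <- map$fusion_groups[[which(vapply(map$fusion_groups,
                                          function(g) "GGA23" %in% g,
                                          logical(1)))]]
  expect_setequal(grp2, c("GGA2", "GGA23", "GGA28"))
  expect_setequal(names(map$status)[map$status == "fused"],
                  cytofish:::fused_labels(km))
  expect_identical(length(map$inconsistencies), 0L)
})

test_that("ancestral karyotypes give all-intact maps with no fusion groups", {
  panel <- build_species_panel()
  for (sp in c("Common ostrich", "Eurasian woodcock")) {
    km <- panel[[sp]]
    sim <- simulate_species_calls(km, n_spreads = 10, drop_rate = 0,
                                  misassign_rate = 0, seed = 3)
    map <- build_rearrangement_map(km$species, sim$pairwise,
                                   sim$carrier_class)
    expect_true(all(map$status == "intact_micro"))
    expect_identical(length(map$fusion_groups), 0L)
  }
})

test_that("maps survive spot dropout and mis-assignment noise", {
  panel <- build_species_panel()
  km <- panel[["Budgerigar"]]
  truth_fused <- cytofish:::fused_labels(km)
  for (rep_seed in 1:20) {
    sim <- simulate_species_calls(km, n_spreads = 10, drop_rate = 0.05,
                                  misassign_rate = 0.02, seed = rep_seed)
    map <- build_rearrangement_map(km$species, sim$pairwise,
                                   sim$carrier_class)
    expect_setequal(names(map$status)[map$status == "fused"], truth_fused)
    expect_identical(length(map$fusion_groups), 6L)
  }
})

test_that("fusion-group partition is invariant to probe-pair ordering", {
  panel <- build_species_panel()
  km <- panel[["Gyrfalcon"]]
  sim <- simulate_species_calls(km, n_spreads = 8, drop_rate = 0,
                                misassign_rate = 0, seed = 4)
  map1 <- build_rearrangement_map(km$species, sim$pairwise,
                                  sim$carrier_class)
  perm <- sim$pairwise[rev(seq_len(nrow(sim$pairwise))), ]
  # also swap a/b columns
  perm2 <- data.frame(a = perm$b, b = perm$a, verdict = perm$verdict,
                      n_same = perm$n_same, n_different = perm$n_different)
  map2 <- build_rearrangement_map(km$species, perm2, sim$carrier_class)
  key <- function(m) sort(vapply(m$fusion_groups, function(g)
    paste(sort(g), collapse = "+"), character(1)))
  expect_identical(key(map1), key(map2))
  expect_identical(map1$status, map2$status)
})

test_that("transitivity conflicts are resolved by majority edge support", {
  pw <- data.frame(a = c("GGA10", "GGA11", "GGA10"),
                   b = c("GGA11", "GGA12", "GGA12"),
                   verdict = c("same", "same", "different"),
                   n_same = c(9, 9, 1), n_different = c(1, 1, 2))
  map <- build_rearrangement_map("test", pw)
  expect_identical(length(map$inconsistencies), 1L)
  expect_identical(map$inconsistencies[[1]]$dropped, "different_edge")
  grp <- map$fusion_groups[[1]]
  expect_setequal(grp, c("GGA10", "GGA11", "GGA12"))
  # reversed support: the weak same-edge goes instead
  pw2 <- data.frame(a = c("GGA10", "GGA11", "GGA10"),
                    b = c("GGA11", "GGA12", "GGA12"),
                    verdict = c("same", "same", "different"),
                    n_same = c(9, 1, 0), n_different = c(1, 1, 8))
  map2 <- build_rearrangement_map("test", pw2)
  expect_identical(map2$inconsistencies[[1]]$dropped, "same_edge")
  expect_setequal(map2$fusion_groups[[1]], c("GGA10", "GGA11"))
})

test_that("probe failures propagate to no_data and do not veto conservation", {
  panel <- build_species_panel()
  kz <- panel[["Zebra finch"]]
  sim <- simulate_species_calls(kz, n_spreads = 6, drop_rate = 0,
                                misassign_rate = 0, seed = 5)
  map <- build_rearrangement_map(kz$species, sim$pairwise,
                                 sim$carrier_class)
  expect_identical(unname(map$status["GGA25"]), "no_data")
  ko <- panel[["Common ostrich"]]
  simo <- simulate_species_calls(ko, n_spreads = 6, drop_rate = 0,
                                 misassign_rate = 0, seed = 6)
  mapo <- build_rearrangement_map(ko$species, simo$pairwise,
                                  simo$carrier_class)
  cons <- conserved_set(list(map, mapo))
  expect_true("GGA25" %in% cons)   # intact in ostrich, no_data in finch
  # a single fused label is excluded
  kb <- panel[["Budgerigar"]]
  simb <- simulate_species_calls(kb, n_spreads = 6, drop_rate = 0,
                                 misassign_rate = 0, seed = 7)
  mapb <- build_rearrangement_map(kb$species, simb$pairwise,
                                  simb$carrier_class)
  expect_false("GGA10" %in% conserved_set(list(mapo, mapb)))
  expect_setequal(conserved_set(list(mapo)), micro_panel_labels())
})

test_that("image-level and call-level mapping agree on a falcon subset", {
  panel <- build_species_panel()
  km <- panel[["Peregrine falcon"]]
  probes <- c("GGA18", "GGA15", "GGA24", "GGA10")
  pairs <- t(combn(probes, 2))
  verdicts <- character(nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    calls <- vapply(1:5, function(s) {
      sc <- render_metaphase_scene(km, pairs[j, ], seed = 100 * j + s,
                                   noise = list(background = 5, sd = 2,
                                                blur_sigma = 1))
      cs <- segment_chromosomes(sc$image$channels$dapi)
      sa <- detect_spots(sc$image$channels$fitc, cs, min_intensity = 800)
      sb <- detect_spots(sc$image$channels$texasred, cs,
                         min_intensity = 800)
      call_pair(sa, sb)
    }, character(1))
    verdicts[j] <- aggregate_calls(calls, pairs[j, ],
                                   min_informative = 4)$verdict
  }
  truth <- apply(pairs, 1, function(pr)
    if (identical(cytofish:::type_of_label(km, pr[1]),
                  cytofish:::type_of_label(km, pr[2]))) "same"
    else "different")
  expect_identical(verdicts, unname(truth))
})
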