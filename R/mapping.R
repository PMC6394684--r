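#' Call whether a probe pair sits on the same chromosome in one spread
#'
#' Uses the chromosome labels assigned to each probe's spots. With the
#' diploid design each probe is expected to yield two assigned spots (one
#' per homolog). The call is:
#' \itemize{
#'   \item `same` — every chromosome marked by one probe is also marked
#'     by the other (one probe's label set is contained in the other's),
#'     so all observed evidence is consistent with co-residence; a spread
#'     where one homolog shows only a single probe (the other spot having
#'     dropped out) still scores `same` when the remaining evidence
#'     co-localizes;
#'   \item `different` — each probe marks two chromosome objects and the
#'     two sets are disjoint;
#'   \item `no_call` — missing spots (e.g. probe failure), unassigned
#'     spots only, or contradictory partial overlap.
#' }
#'
#' @param spots_a,spots_b [detect_spots()] tables (or any data.frame with
#'   a `label` column; label 0 = unassigned).
#' @param chromosomes unused placeholder for API symmetry; assignments are
#'   carried by the spot tables.
#' @return one of `"same"`, `"different"`, `"no_call"`.
#' @export
call_pair <- function(spots_a, spots_b, chromosomes = NULL) {
  la <- unique(spots_a$label[spots_a$label > 0])
  lb <- unique(spots_b$label[spots_b$label > 0])
  if (length(la) == 0 || length(lb) == 0) return("no_call")
  if (all(la %in% lb) || all(lb %in% la)) return("same")
  if (length(la) == 2 && length(lb) == 2 &&
      length(intersect(la, lb)) == 0) return("different")
  "no_call"
}

#' Aggregate per-spread pair calls into a fusion call
#'
#' A probe pair's verdict is `same` or `different` when at least
#' `min_informative` spreads gave an informative (non-`no_call`) call and
#' the winning category holds at least a `majority` fraction of the
#' informative calls; otherwise `no_data`.
#'
#' @param calls character vector of per-spread calls.
#' @param probe_pair length-2 character vector of GGA labels (metadata).
#' @param min_informative minimum informative spreads (default 5).
#' @param majority winning fraction of informative calls (default 0.8).
#' @return object of class `fusion_call` with counts and `verdict`.
#' @export
aggregate_calls <- function(calls, probe_pair = c(NA, NA),
                            min_informative = 5L, majority = 0.8) {
  calls <- as.character(calls)
  stopifnot(all(calls %in% c("same", "different", "no_call")))
  n_same <- sum(calls == "same")
  n_diff <- sum(calls == "different")
  n_nc <- sum(calls == "no_call")
  informative <- n_same + n_diff
  verdict <- "no_data"
  if (informative >= min_informative) {
    if (n_same / informative >= majority) verdict <- "same"
    else if (n_diff / informative >= majority) verdict <- "different"
  }
  structure(list(probe_pair = probe_pair, n_spreads = length(calls),
                 n_same = n_same, n_different = n_diff, n_no_call = n_nc,
                 verdict = verdict), class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  cat("<fusion_call> ", paste(x$probe_pair, collapse = " vs "), ": ",
      x$verdict, " (", x$n_same, " same / ", x$n_different,
      " different / ", x$n_no_call, " no-call)\n", sep = "")
  invisible(x)
}

# union-find helpers for fusion-group construction
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build a per-species rearrangement map from pairwise fusion calls
#'
#' Treats probe labels as graph nodes and `same` verdicts as edges;
#' connected components with two or more labels are fusion groups.
#' Transitivity conflicts (a `different` verdict inside a component) are
#' recorded as inconsistencies and resolved by majority edge support: the
#' conflicting edge with the weakest informative support is discarded and
#' components are rebuilt.
#'
#' Each panel microchromosome's status is then:
#' \itemize{
#'   \item `fused` — it belongs to a fusion group, or its spots sit on a
#'     macro-class carrier (a micro fused alone to a macrochromosome);
#'   \item `intact_micro` — spot evidence exists and the carrier is
#'     micro-class, with no fusion partner;
#'   \item `no_data` — no informative evidence (probe failure or missing
#'     pairs).
#' }
#'
#' @param species species name (metadata).
#' @param pairwise data.frame with columns `a`, `b`, `verdict`, and
#'   support counts `n_same`, `n_different` (one row per probe pair).
#' @param carrier_class optional data.frame `label`, `class`
#'   (`"macro"`/`"micro"`) giving the majority size class of the
#'   chromosome carrying each probe's spots; enables fused status for
#'   micros fused alone to a macrochromosome.
#' @param panel probe labels the status map must cover (default the
#'   chicken microchromosome panel).
#' @return object of class `rearrangement_map`: `status` (named vector
#'   over `panel`), `fusion_groups` (list of label sets, macro host labels
#'   included when probed), `inconsistencies`, `completeness` (fraction of
#'   panel pairs with informative verdicts).
#' @export
build_rearrangement_map <- function(species, pairwise, carrier_class = NULL,
                                    panel = micro_panel_labels()) {
  stopifnot(is.data.frame(pairwise),
            all(c("a", "b", "verdict") %in% names(pairwise)))
  if (!"n_same" %in% names(pairwise)) pairwise$n_same <- 0L
  if (!"n_different" %in% names(pairwise)) pairwise$n_different <- 0L
  labels <- sort(unique(c(pairwise$a, pairwise$b, panel)))
  edges <- pairwise[pairwise$verdict == "same", , drop = FALSE]
  diffs <- pairwise[pairwise$verdict == "different", , drop = FALSE]

  inconsistencies <- list()
  repeat {
    parent <- seq_along(labels); names(parent) <- labels
    for (i in seq_len(nrow(edges))) {
      ra <- uf_find(parent, match(edges$a[i], labels))
      rb <- uf_find(parent, match(edges$b[i], labels))
      if (ra != rb) parent[rb] <- ra
    }
    comp <- vapply(seq_along(labels), function(i) uf_find(parent, i),
                   integer(1))
    conflict <- NULL
    for (i in seq_len(nrow(diffs))) {
      ia <- match(diffs$a[i], labels); ib <- match(diffs$b[i], labels)
      if (comp[ia] == comp[ib]) { conflict <- i; break }
    }
    if (is.null(conflict)) break
    # majority support: drop whichever of the conflicting relations is
    # weakest — the different-edge, or the weakest same-edge in the
    # offending component
    d_support <- diffs$n_different[conflict]
    in_comp <- comp[match(edges$a, labels)] == comp[match(diffs$a[conflict],
                                                          labels)]
    s_min <- which(in_comp)[which.min(edges$n_same[in_comp])]
    inconsistencies[[length(inconsistencies) + 1L]] <-
      list(pair = c(diffs$a[conflict], diffs$b[conflict]),
           dropped = if (d_support <= edges$n_same[s_min]) "different_edge"
                     else "same_edge")
    if (d_support <= edges$n_same[s_min]) {
      diffs <- diffs[-conflict, , drop = FALSE]
    } else {
      edges <- edges[-s_min, , drop = FALSE]
    }
  }

  groups <- split(labels, comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2])
  groups <- lapply(groups, sort)

  # informative evidence per label
  informative <- setNames(rep(FALSE, length(labels)), labels)
  for (i in seq_len(nrow(pairwise)))
    if (pairwise$verdict[i] %in% c("same", "different")) {
      informative[pairwise$a[i]] <- TRUE
      informative[pairwise$b[i]] <- TRUE
    }

  in_group <- setNames(rep(FALSE, length(labels)), labels)
  for (g in groups) in_group[g] <- TRUE

  status <- setNames(rep("no_data", length(panel)), panel)
  for (lb in panel) {
    if (!informative[lb]) next
    cls <- if (!is.null(carrier_class) && lb %in% carrier_class$label)
      carrier_class$class[match(lb, carrier_class$label)] else NA_character_
    status[lb] <- if (in_group[lb] || identical(cls, "macro")) "fused"
                  else "intact_micro"
  }

  pp <- pairwise[pairwise$a %in% panel & pairwise$b %in% panel, ,
                 drop = FALSE]
  completeness <- if (nrow(pp) == 0) 0 else
    mean(pp$verdict %in% c("same", "different"))

  structure(list(species = species, status = status,
                 fusion_groups = groups,
                 inconsistencies = inconsistencies,
                 completeness = completeness, pairwise = pairwise),
            class = "rearrangement_map")
}

#' @export
print.rearrangement_map <- function(x, ...) {
  cat("<rearrangement_map> ", x$species, "\n", sep = "")
  cat("  fused: ", sum(x$status == "fused"),
      "  intact: ", sum(x$status == "intact_micro"),
      "  no data: ", sum(x$status == "no_data"),
      "  (completeness ", round(x$completeness, 3), ")\n", sep = "")
  for (g in x$fusion_groups)
    cat("  group:", paste(g, collapse = " + "), "\n")
  if (length(x$inconsistencies))
    cat("  ", length(x$inconsistencies), " transitivity conflict(s) resolved\n")
  invisible(x)
}

#' Microchromosomes conserved across a set of species maps
#'
#' Returns the panel labels whose status is `intact_micro` in every
#' species where data exist; species with `no_data` for a label do not
#' veto it.
#'
#' @param maps list of [build_rearrangement_map()] results.
#' @return character vector of conserved GGA labels.
#' @export
conserved_set <- function(maps) {
  stopifnot(length(maps) >= 1)
  panel <- names(maps[[1]]$status)
  keep <- rep(TRUE, length(panel)); names(keep) <- panel
  seen <- rep(FALSE, length(panel)); names(seen) <- panel
  for (m in maps) {
    st <- m$status[panel]
    seen <- seen | st != "no_data"
    keep <- keep & (st != "fused")
    keep <- keep & (st %in% c("intact_micro", "no_data"))
  }
  sort(panel[keep & seen])
}

#' Simulate per-spread pair calls for one species at the call level
#'
#' Runs the all-vs-all co-hybridization design directly on the karyotype's
#' ground-truth spot assignments, without rasterizing images: every probe
#' yields one spot per homologous chromosome copy, each spot is dropped
#' with probability `drop_rate` (hybridization failure) and re-assigned to
#' a uniformly chosen wrong chromosome object with probability
#' `misassign_rate` (segmentation/assignment error). Probes listed in the
#' karyotype's `probe_failures` yield no spots. This is the fast
#'stand-alone route for panel-scale mapping; image-level rendering
#' ([render_metaphase_scene()] + [segment_chromosomes()] +
#' [detect_spots()]) exercises the same calling path end to end.
#'
#' @param karyotype a [karyotype_model()].
#' @param n_spreads spreads per probe pair (default 10).
#' @param drop_rate per-spot dropout probability.
#' @param misassign_rate per-spot mis-assignment probability.
#' @param seed RNG seed.
#' @param include_macros also probe the nine macrochromosome labels (so
#'   fusion groups name their host macrochromosome)?
#' @param min_informative,majority aggregation thresholds, see
#'   [aggregate_calls()].
#' @return list: `pairwise` (data.frame a, b, verdict, support counts),
#'   `carrier_class` (majority carrier size class per label), `species`.
#' @export
simulate_species_calls <- function(karyotype, n_spreads = 10L,
                                   drop_rate = 0.05, misassign_rate = 0.02,
                                   seed = 1L, include_macros = TRUE,
                                   min_informative = 5L, majority = 0.8) {
  stopifnot(inherits(karyotype, "karyotype_model"))
  chrom <- karyotype$chromosomes
  n_obj <- 2L * nrow(chrom)                    # object = (type, copy)
  obj_type <- rep(seq_len(nrow(chrom)), each = 2L)
  obj_class <- chrom$class[obj_type]
  labels <- micro_panel_labels()
  if (include_macros) labels <- c(macro_labels(), labels)

  with_seed(seed, {
    # per label: the two ground-truth carrier objects (or NULL on failure)
    carriers <- lapply(labels, function(lb) {
      if (lb %in% karyotype$probe_failures) return(integer())
      ti <- type_of_label(karyotype, lb)
      if (is.na(ti)) return(integer())
      which(obj_type == ti)
    })
    names(carriers) <- labels

    observe <- function(lb) {
      objs <- carriers[[lb]]
      if (!length(objs)) return(integer())
      kept <- objs[runif(length(objs)) >= drop_rate]
      if (!length(kept)) return(integer())
      flip <- runif(length(kept)) < misassign_rate
      kept[flip] <- sample.int(n_obj, sum(flip), replace = TRUE)
      kept
    }

    pairs <- utils::combn(labels, 2)
    verdicts <- character(ncol(pairs))
    n_same <- integer(ncol(pairs)); n_diff <- integer(ncol(pairs))
    n_spr <- integer(ncol(pairs))
    class_votes <- lapply(labels, function(...) character())
    names(class_votes) <- labels

    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      calls <- character(n_spreads)
      for (s in seq_len(n_spreads)) {
        oa <- observe(a); ob <- observe(b)
        calls[s] <- call_pair(data.frame(label = oa),
                              data.frame(label = ob))
        class_votes[[a]] <- c(class_votes[[a]], obj_class[oa])
        class_votes[[b]] <- c(class_votes[[b]], obj_class[ob])
      }
      fc <- aggregate_calls(calls, c(a, b), min_informative, majority)
      verdicts[j] <- fc$verdict
      n_same[j] <- fc$n_same; n_diff[j] <- fc$n_different
      n_spr[j] <- fc$n_spreads
    }
    carrier <- data.frame(
      label = labels,
      class = vapply(labels, function(lb) {
        v <- class_votes[[lb]]
        if (!length(v)) NA_character_
        else names(sort(table(v), decreasing = TRUE))[1]
      }, character(1)))
    list(pairwise = data.frame(a = pairs[1, ], b = pairs[2, ],
                               verdict = verdicts, n_same = n_same,
                               n_different = n_diff, n_spreads = n_spr),
         carrier_class = carrier[!is.na(carrier$class), , drop = FALSE],
         species = karyotype$species)
  })
}

#' Run the full species panel and infer all rearrangement maps
#'
#' For every species in the panel, simulates the all-vs-all probe-pair
#' design ([simulate_species_calls()]) and builds the rearrangement map.
#'
#' @param panel list of karyotypes from [build_species_panel()].
#' @param n_spreads spreads per probe pair.
#' @param drop_rate,misassign_rate noise model, see
#'   [simulate_species_calls()].
#' @param seed RNG seed; each species derives its own child stream.
#' @param include_macros probe macro labels too (default TRUE).
#' @return named list of [build_rearrangement_map()] results.
#' @export
run_species_panel <- function(panel, n_spreads = 10L, drop_rate = 0.05,
                              misassign_rate = 0.02, seed = 1L,
                              include_macros = TRUE) {
  maps <- list()
  for (i in seq_along(panel)) {
    km <- panel[[i]]
    sim <- simulate_species_calls(km, n_spreads, drop_rate, misassign_rate,
                                  seed = child_seed(seed, i),
                                  include_macros = include_macros)
    maps[[km$species]] <- build_rearrangement_map(km$species, sim$pairwise,
                                                  sim$carrier_class)
  }
  maps
}

#' Serialize a rearrangement map to JSON / flat TSV
#'
#' @param map a [build_rearrangement_map()] result.
#' @param path output path (`.json` or `.tsv` decides nothing; use the
#'   dedicated function for each format).
#' @export
write_map_json <- function(map, path) {
  jsonlite::write_json(list(species = map$species,
                            status = as.list(map$status),
                            fusion_groups = map$fusion_groups,
                            completeness = map$completeness,
                            n_inconsistencies = length(map$inconsistencies)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_map_json
#' @param maps named list of maps.
#' @export
write_maps_tsv <- function(maps, path) {
  df <- do.call(rbind, lapply(maps, function(m) {
    grp <- vapply(names(m$status), function(lb) {
      hit <- which(vapply(m$fusion_groups, function(g) lb %in% g,
                          logical(1)))
      if (length(hit)) paste(m$fusion_groups[[hit[1]]], collapse = "+")
      else ""
    }, character(1))
    data.frame(species = m$species, label = names(m$status),
               status = unname(m$status), fusion_group = unname(grp))
  }))
  rownames(df) <- NULL
  write_tsv(df, path)
}

#' @rdname write_map_json
#' @param pairwise_list named (by species) list of pairwise call tables.
#' @export
write_calls_tsv <- function(pairwise_list, path) {
  df <- do.call(rbind, lapply(names(pairwise_list), function(sp) {
    pw <- pairwise_list[[sp]]
    data.frame(species = sp, pw)
  }))
  rownames(df) <- NULL
  write_tsv(df, path)
}
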