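#' Run a pipeline stage from a configuration
#'
#' Single programmatic entry point behind the command-line wrapper
#' (`inst/scripts/cytofish`). The configuration is a named list (or a YAML
#' file with the same structure) with a `subcommand` plus that
#' subcommand's parameters; unknown keys are rejected. Every stage writes
#' its module's TSV/JSON outputs into `out_dir` together with a
#' `manifest.json` echoing the configuration and seed, so any output is
#' reproducible from its manifest alone. On failure, partially written
#' outputs of the failed run are removed.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate-interphase`}{render an interphase scene; writes
#'     `interphase.tif` (+ sidecar), `truth_spots.tsv`.}
#'   \item{`simulate-metaphase`}{render a metaphase spread for one species
#'     and probe pair; writes `metaphase.tif`, `truth_spots.tsv`.}
#'   \item{`shells`}{segment an interphase image and measure per-nucleus
#'     shell profiles; writes `nuclei.tsv`, `profiles.tsv`.}
#'   \item{`stats`}{read one or more profile TSVs (groups), run the
#'     vs-random and between-group chi-square tests with Bonferroni
#'     correction; writes `results.tsv`.}
#'   \item{`map`}{simulate calls and build the rearrangement map for one
#'     species of the panel; writes `map_<species>.json`, `calls.tsv`.}
#'   \item{`panel`}{end-to-end panel run over every species; writes one
#'     map JSON per species plus `maps.tsv`, `calls.tsv`,
#'     `conserved.json`.}
#' }
#'
#' @param config named list or path to a YAML config file. Common keys:
#'   `subcommand`, `out_dir`, `seed`, `n_shells`, `pseudo_n`; see the
#'   vignette for per-subcommand parameters.
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("missing input file: '", config, "'")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$subcommand))
  sub <- config$subcommand
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }

  known <- list(
    "simulate-interphase" = c("subcommand", "out_dir", "seed", "n_nuclei",
                              "placement", "shell_weights", "beta_params",
                              "noise", "nucleus_radius", "spots_per_territory",
                              "territories_per_probe"),
    "simulate-metaphase" = c("subcommand", "out_dir", "seed", "species",
                             "probe_a", "probe_b", "noise", "panel_file"),
    "shells" = c("subcommand", "out_dir", "image", "n_shells", "mode",
                 "min_area", "min_circularity", "probe_channel",
                 "normalization"),
    "stats" = c("subcommand", "out_dir", "profiles", "groups", "pseudo_n"),
    "map" = c("subcommand", "out_dir", "seed", "species", "n_spreads",
              "drop_rate", "misassign_rate", "panel_file"),
    "panel" = c("subcommand", "out_dir", "seed", "n_spreads", "drop_rate",
                "misassign_rate", "panel_file"))
  if (!sub %in% names(known)) stop("unknown subcommand: ", sub)
  unknown <- setdiff(names(config), known[[sub]])
  if (length(unknown))
    stop("unknown config keys for '", sub, "': ",
         paste(unknown, collapse = ", "))

  run <- function() {
    seed <- config$seed %||% 1L
    switch(sub,
      "simulate-interphase" = {
        placement <- switch(config$placement %||% "uniform_area",
          uniform_area = radial_placement("uniform_area"),
          shell_weights = radial_placement("shell_weights",
            shell_weights = as.numeric(config$shell_weights)),
          beta_radial = radial_placement("beta_radial",
            beta_params = as.numeric(config$beta_params)))
        spec <- interphase_spec(
          n_nuclei = config$n_nuclei %||% 20L,
          placement = placement,
          noise = config$noise %||% list(background = 5, sd = 2,
                                         blur_sigma = 1),
          spots_per_territory = config$spots_per_territory %||% 3L,
          territories_per_probe = config$territories_per_probe %||% 2L)
        scene <- render_interphase_scene(spec, seed)
        write_image(scene$image, emit(file.path(out_dir, "interphase.tif")))
        emit(file.path(out_dir, "interphase.tif.meta.json"))
        sp <- scene$truth$spots
        sp$object_id <- sp$nucleus_id
        write_truth_tsv(list(spots = sp),
                        emit(file.path(out_dir, "truth_spots.tsv")),
                        scene_id = "interphase")
      },
      "simulate-metaphase" = {
        panel <- build_species_panel(config$panel_file)
        km <- panel[[config$species %||% "Peregrine falcon"]]
        if (is.null(km)) stop("unknown species: ", config$species)
        scene <- render_metaphase_scene(km,
          c(config$probe_a %||% "GGA18", config$probe_b %||% "GGA24"),
          seed, noise = config$noise %||% list(background = 5, sd = 2,
                                               blur_sigma = 1))
        write_image(scene$image, emit(file.path(out_dir, "metaphase.tif")))
        emit(file.path(out_dir, "metaphase.tif.meta.json"))
        write_truth_tsv(scene$truth,
                        emit(file.path(out_dir, "truth_spots.tsv")),
                        scene_id = km$species)
      },
      "shells" = {
        if (is.null(config$image)) stop("missing input file: config$image")
        img <- read_image(config$image)
        ns <- segment_counterstain(img$channels$dapi)
        ns <- filter_nuclei(ns, min_area_px = config$min_area %||% 500,
                            min_circularity = config$min_circularity %||% 0.6)
        write_nuclei_tsv(ns, emit(file.path(out_dir, "nuclei.tsv")))
        S <- config$n_shells %||% 5L
        pc <- config$probe_channel %||% "probe"
        profs <- lapply(ns$objects$label, function(lb) {
          om <- object_mask(ns, lb)
          rows <- om$row_offset + seq_len(nrow(om$mask)) - 1L
          cols <- om$col_offset + seq_len(ncol(om$mask)) - 1L
          rk <- rows >= 1 & rows <= nrow(img$channels[[pc]])
          ck <- cols >= 1 & cols <= ncol(img$channels[[pc]])
          shells <- compute_shells(om$mask[rk, ck, drop = FALSE], S,
                                   config$mode %||% "equal_area")
          measure_profile(shells,
                          img$channels[[pc]][rows[rk], cols[ck],
                                             drop = FALSE],
                          background_subtract = TRUE)
        })
        write_profiles_tsv(profs, emit(file.path(out_dir, "profiles.tsv")),
                           labels = ns$objects$label)
      },
      "stats" = {
        paths <- config$profiles
        if (is.null(paths)) stop("missing input file: config$profiles")
        for (p in paths) if (!file.exists(p))
          stop("missing input file: '", p, "'")
        groups <- config$groups %||% paste0("group", seq_along(paths))
        aggs <- mapply(function(p, g) {
          df <- read.delim(p, comment.char = "#")
          shell_cols <- grep("^shell_", names(df))
          profs <- lapply(seq_len(nrow(df)), function(i) {
            structure(list(proportions = as.numeric(df[i, shell_cols]),
                           shell_sums = as.numeric(df[i, shell_cols]) *
                             df$total_signal[i],
                           total_signal = df$total_signal[i],
                           n_shells = length(shell_cols),
                           probe_name = df$probe[i],
                           normalization = df$normalization[i]),
                      class = "signal_profile")
          })
          aggregate_profiles(profs, g)
        }, paths, groups, SIMPLIFY = FALSE)
        pseudo_n <- config$pseudo_n %||% 100L
        res <- lapply(aggs, chisq_vs_random,
                      pseudo_n_per_nucleus = pseudo_n)
        if (length(aggs) >= 2) {
          between <- list()
          for (i in seq_along(aggs)) for (j in seq_along(aggs))
            if (i < j) between[[length(between) + 1L]] <-
              chisq_groups(aggs[[i]], aggs[[j]], pseudo_n)
          padj <- adjust_bonferroni(vapply(between, `[[`, numeric(1),
                                           "p_raw"))
          for (k in seq_along(between)) between[[k]]$p_adjusted <- padj[k]
          res <- c(res, between)
        }
        write_results_tsv(res, emit(file.path(out_dir, "results.tsv")))
      },
      "map" = {
        panel <- build_species_panel(config$panel_file)
        km <- panel[[config$species %||% stop("config$species required")]]
        if (is.null(km)) stop("unknown species: ", config$species)
        sim <- simulate_species_calls(km,
          n_spreads = config$n_spreads %||% 10L,
          drop_rate = config$drop_rate %||% 0.05,
          misassign_rate = config$misassign_rate %||% 0.02, seed = seed)
        map <- build_rearrangement_map(km$species, sim$pairwise,
                                       sim$carrier_class)
        write_map_json(map, emit(file.path(out_dir,
          paste0("map_", gsub("[^A-Za-z0-9]+", "_", km$species), ".json"))))
        write_calls_tsv(setNames(list(sim$pairwise), km$species),
                        emit(file.path(out_dir, "calls.tsv")))
      },
      "panel" = {
        panel <- build_species_panel(config$panel_file)
        maps <- run_species_panel(panel,
          n_spreads = config$n_spreads %||% 10L,
          drop_rate = config$drop_rate %||% 0.05,
          misassign_rate = config$misassign_rate %||% 0.02, seed = seed)
        for (m in maps)
          write_map_json(m, emit(file.path(out_dir,
            paste0("map_", gsub("[^A-Za-z0-9]+", "_", m$species),
                   ".json"))))
        write_maps_tsv(maps, emit(file.path(out_dir, "maps.tsv")))
        write_calls_tsv(lapply(maps, `[[`, "pairwise"),
                        emit(file.path(out_dir, "calls.tsv")))
        jsonlite::write_json(conserved_set(maps),
                             emit(file.path(out_dir, "conserved.json")))
      })
    write_manifest(emit(file.path(out_dir, "manifest.json")), config, seed,
                   basename(written))
  }

  tryCatch(run(), error = function(e) {
    unlink(written)
    stop(conditionMessage(e), call. = FALSE)
  })
  message("[cytofish] ", sub, ": wrote ", length(written),
          " file(s) to ", out_dir)
  invisible(written)
}
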