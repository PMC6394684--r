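#' Chicken microchromosome probe panel
#'
#' The reference probe panel covers chicken (GGA) microchromosomes 10-28
#' with the exception of GGA16, for which no universal BAC probes exist.
#'
#' @return character vector of GGA labels.
#' @export
micro_panel_labels <- function() paste0("GGA", setdiff(10:28, 16))

macro_labels <- function() paste0("GGA", 1:9)

# default rendered lengths (px) for the nine labelled macrochromosomes and
# the probed microchromosomes; filler (unprobed) chromosomes interpolate
default_macro_lengths <- function()
  setNames(c(260, 230, 200, 180, 160, 140, 120, 105, 90), macro_labels())

default_micro_length <- function(label) {
  k <- as.integer(sub("GGA", "", label))
  round(34 - 0.7 * (k - 10))          # 34 px (GGA10) down to ~21 px (GGA28)
}

#' Construct a species karyotype model
#'
#' A karyotype model lists one entry per chromosome *type* (each rendered
#' twice in a diploid metaphase spread): its length in pixels, its size
#' class (`macro`/`micro`), and the set of GGA homolog labels it carries.
#' An ancestral microchromosome that fused to a macrochromosome appears as
#' an extra label in that macrochromosome's content.
#'
#' @param species species (common) name.
#' @param diploid_number 2n; must be even and equal to twice the number of
#'   chromosome types.
#' @param chromosomes data.frame with columns `type`, `length_px`, `class`
#'   and a list-column `content` of character label vectors.
#' @param probe_failures GGA labels whose probes yield no signal in this
#'   species.
#' @return object of class `karyotype_model`.
#' @export
karyotype_model <- function(species, diploid_number, chromosomes,
                            probe_failures = character()) {
  stopifnot(is.character(species), length(species) == 1,
            is.numeric(diploid_number), diploid_number > 0)
  if (diploid_number %% 2 != 0)
    stop("validation error: diploid number must be even")
  stopifnot(is.data.frame(chromosomes),
            all(c("type", "length_px", "class", "content") %in%
                  names(chromosomes)))
  if (nrow(chromosomes) * 2 != diploid_number)
    stop("validation error: ", nrow(chromosomes), " chromosome types need ",
         "diploid number ", nrow(chromosomes) * 2, ", got ", diploid_number)
  labs <- unlist(chromosomes$content)
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop("validation error: labels on multiple chromosome types: ",
         paste(unique(dup), collapse = ", "))
  structure(list(species = species,
                 diploid_number = as.integer(diploid_number),
                 chromosomes = chromosomes,
                 probe_failures = probe_failures),
            class = "karyotype_model")
}

#' @export
print.karyotype_model <- function(x, ...) {
  fused <- fused_labels(x)
  cat("<karyotype_model> ", x$species, " (2n = ", x$diploid_number, ")\n",
      sep = "")
  cat("  fused panel micros: ",
      if (length(fused)) paste(fused, collapse = ", ") else "none", "\n",
      sep = "")
  if (length(x$probe_failures))
    cat("  probe failures:", paste(x$probe_failures, collapse = ", "), "\n")
  invisible(x)
}

# panel micro labels that sit on a chromosome carrying other labels too
fused_labels <- function(karyotype) {
  panel <- micro_panel_labels()
  out <- character()
  for (ct in karyotype$chromosomes$content)
    if (length(ct) > 1) out <- c(out, intersect(ct, panel))
  sort(out)
}

# chromosome type index carrying a label, or NA
type_of_label <- function(karyotype, label) {
  hit <- which(vapply(karyotype$chromosomes$content,
                      function(ct) label %in% ct, logical(1)))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# Build one karyotype from a panel config entry: 9 labelled macros,
# intact panel micros, filler chromosomes to reach 2n; fusion groups are a
# named list host-macro-label -> fused micro labels.
build_karyotype <- function(species, diploid_number, fusions = list(),
                            probe_failures = character()) {
  K <- diploid_number / 2
  mac <- default_macro_lengths()
  panel <- micro_panel_labels()
  fused <- unlist(fusions, use.names = FALSE)
  bad <- setdiff(fused, panel)
  if (length(bad))
    stop("configuration error: unknown fused labels ",
         paste(bad, collapse = ", "))
  bad_host <- setdiff(names(fusions), macro_labels())
  if (length(bad_host))
    stop("configuration error: unknown macro hosts ",
         paste(bad_host, collapse = ", "))
  intact <- setdiff(panel, fused)
  n_filler <- K - length(mac) - length(intact)
  if (n_filler < 0)
    stop("validation error: 2n = ", diploid_number,
         " too small for panel composition")
  rows <- list()
  for (m in names(mac))
    rows[[length(rows) + 1L]] <- list(length_px = unname(mac[m]),
      class = "macro", content = c(m, unname(fusions[[m]])))
  for (lb in intact)
    rows[[length(rows) + 1L]] <- list(length_px = default_micro_length(lb),
      class = "micro", content = lb)
  if (n_filler > 0)
    for (j in seq_len(n_filler))
      rows[[length(rows) + 1L]] <- list(
        length_px = round(seq(40, 16, length.out = max(n_filler, 2)))[j],
        class = "micro", content = character())
  chrom <- data.frame(type = seq_along(rows),
                      length_px = vapply(rows, `[[`, numeric(1), "length_px"),
                      class = vapply(rows, `[[`, character(1), "class"))
  chrom$content <- lapply(rows, `[[`, "content")
  karyotype_model(species, diploid_number, chrom, probe_failures)
}

# The shipped species panel: 22 avian species across 10 orders with their
# published diploid numbers; falcons share one fusion configuration
# (panel micros 10,12,13,14,15,17,18,19,21,23,28 on macrochromosomes, with
# 15+18+19 together on the GGA4 homolog and 23+28 together on the GGA2
# homolog); the budgerigar fuses 10,11,14 and additionally 12,13,17; the
# cockatiel and red-crowned parakeet fuse 10,11,14 (GGA11 to the GGA1
# homolog); all other species keep the ancestral pattern. GGA25 probes
# fail on the zebra finch, blackbird and canary.
default_panel_config <- function() {
  falcon_fusions <- list(GGA4 = c("GGA15", "GGA18", "GGA19"),
                         GGA2 = c("GGA23", "GGA28"),
                         GGA1 = "GGA10", GGA3 = "GGA12", GGA5 = "GGA13",
                         GGA6 = "GGA14", GGA7 = "GGA17", GGA8 = "GGA21")
  budgie_fusions <- list(GGA1 = "GGA10", GGA2 = "GGA11", GGA3 = "GGA14",
                         GGA4 = "GGA12", GGA5 = "GGA13", GGA6 = "GGA17")
  small_parrot_fusions <- list(GGA2 = "GGA10", GGA1 = "GGA11",
                               GGA3 = "GGA14")
  sp <- function(order, common, species, n2, fusions = list(),
                 probe_failures = character())
    list(order = order, common_name = common, species_name = species,
         diploid_number = as.integer(n2), fusions = fusions,
         probe_failures = probe_failures)
  list(
    sp("Anseriformes", "Mallard", "Anas platyrhynchos", 80),
    sp("Charadriiformes", "Eurasian woodcock", "Scolopax rusticola", 96),
    sp("Columbiformes", "Rock dove", "Columba livia", 80),
    sp("Columbiformes", "Eurasian collared dove", "Streptopelia decaocto", 76),
    sp("Falconiformes", "Peregrine falcon", "Falco peregrinus", 50,
       falcon_fusions),
    sp("Falconiformes", "Saker falcon", "Falco cherrug", 52, falcon_fusions),
    sp("Falconiformes", "Gyrfalcon", "Falco rusticolus", 52, falcon_fusions),
    sp("Galliformes", "Turkey", "Meleagris gallopavo", 80),
    sp("Galliformes", "Chinese quail", "Coturnix chinensis", 78),
    sp("Galliformes", "Japanese quail", "Coturnix japonica", 78),
    sp("Galliformes", "Guinea fowl", "Numida meleagris", 78),
    sp("Galliformes", "Indian peafowl", "Pavo cristatus", 78),
    sp("Galliformes", "Sand partridge", "Ammoperdix heyi", 78),
    sp("Otidiformes", "Houbara bustard", "Chlamydotis undulata", 76),
    sp("Passeriformes", "Common blackbird", "Turdus merula", 80,
       probe_failures = "GGA25"),
    sp("Passeriformes", "Atlantic canary", "Serinus canaria", 80,
       probe_failures = "GGA25"),
    sp("Passeriformes", "Zebra finch", "Taeniopygia guttata", 80,
       probe_failures = "GGA25"),
    sp("Psittaciformes", "Budgerigar", "Melopsittacus undulatus", 62,
       budgie_fusions),
    sp("Psittaciformes", "Cockatiel", "Nymphicus hollandicus", 72,
       small_parrot_fusions),
    sp("Psittaciformes", "Red-crowned parakeet",
       "Cyanoramphus novaezelandiae", 70, small_parrot_fusions),
    sp("Strigiformes", "Pharaoh eagle-owl", "Bubo ascalaphus", 72),
    sp("Struthioniformes", "Common ostrich", "Struthio camelus", 80)
  )
}

#' Build the species karyotype panel
#'
#' Converts a panel configuration (by default the shipped 22-species avian
#' panel; alternatively a YAML file of the same structure) into a list of
#' [karyotype_model()] objects, one per species, keyed by common name.
#'
#' @param config `NULL` for the shipped default panel, a path to a YAML
#'   panel file, or a pre-parsed list of species entries (each with
#'   `common_name`, `species_name`, `order`, `diploid_number`, optional
#'   `fusions` (named list host macro -> fused GGA labels) and
#'   `probe_failures`).
#' @return named list of `karyotype_model`s.
#' @examples
#' panel <- build_species_panel()
#' panel[["Peregrine falcon"]]$diploid_number  # 50
#' @export
build_species_panel <- function(config = NULL) {
  if (is.null(config)) {
    entries <- default_panel_config()
  } else if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("missing input file: '", config, "'")
    entries <- yaml::read_yaml(config)$species
  } else entries <- config
  out <- list()
  for (e in entries) {
    fus <- lapply(e$fusions %||% list(), unlist)
    km <- build_karyotype(e$common_name, e$diploid_number, fus,
                          unlist(e$probe_failures %||% character()))
    km$species_name <- e$species_name %||% NA_character_
    km$order <- e$order %||% NA_character_
    out[[e$common_name]] <- km
  }
  out
}

#' Write a panel configuration to YAML
#'
#' Serializes a panel (list of config entries, as produced internally for
#' the default panel) so users can edit species, diploid numbers or fusion
#' assignments and feed the file back to [build_species_panel()].
#'
#' @param path output YAML path.
#' @param config panel entries; default the shipped panel.
#' @export
write_panel_yaml <- function(path, config = default_panel_config()) {
  yaml::write_yaml(list(species = config), path)
  invisible(path)
}
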