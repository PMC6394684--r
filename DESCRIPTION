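Package: cytofish
Title: Simulation and Analysis of FISH Images for Avian Microchromosome
    Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two computational procedures of comparative avian
    cytogenetics. First, concentric-shell analysis of fluorescence in situ
    hybridization (FISH) signal position in interphase nuclei: nuclei are
    segmented from a DAPI counterstain channel, decomposed into equal-area
    (or fixed-erosion) concentric shells indexed 0 (peripheral) to S-1
    (central), per-shell signal proportions are measured and tested against
    a random radial pattern and between fused/unfused species groups with
    chi-square tests and Bonferroni correction. Second, metaphase
    co-hybridization mapping: two-colour BAC probe signals on metaphase
    spreads are assigned to segmented chromosomes, same/different-chromosome
    calls are aggregated across spreads, and per-species chromosome
    rearrangement maps (microchromosome fusion groups) are inferred. A
    synthetic-imaging module generates both image classes with full ground
    truth, including a configurable panel of avian karyotypes, so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
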