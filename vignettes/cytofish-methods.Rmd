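---
title: "Methods: shell analysis of nuclear FISH position and metaphase fusion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shell analysis of nuclear FISH position and metaphase fusion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofish)
```

# Scope

`cytofish` implements two computational procedures of comparative avian
cytogenetics, and a synthetic-imaging module that makes both testable end
to end without any external image data:

1. **Interphase radial positioning.** Where does a FISH-probed chromosome
   territory sit within the nucleus — peripheral or central? The package
   segments nuclei from a DAPI counterstain, divides each nucleus into
   concentric shells, measures the per-shell proportion of probe signal,
   and tests radial distributions against a random pattern and between
   pooled groups of species (those where the probed microchromosome has
   fused to a macrochromosome versus those where it has not), with
   Bonferroni correction across the family of between-group tests.
2. **Metaphase fusion mapping.** Which ancestral microchromosomes have
   fused to larger chromosomes in which species? Two-colour BAC probe
   signals on metaphase spreads are assigned to segmented chromosomes;
   per-spread same/different-chromosome calls are aggregated over spreads
   and over the all-vs-all probe-pair design into a per-species
   rearrangement map.

# The interphase model

## Shell decomposition

A nucleus mask is partitioned into $S$ concentric shells indexed $0$
(most peripheral) to $S-1$ (most central); the default $S = 5$ matches
the convention of radial-positioning bar charts. The radial coordinate of
a pixel is its Euclidean distance to the nearest background pixel
(distance-to-boundary transform), which makes the decomposition
shape-independent: it follows the outline of an elliptical or rippled
nucleus rather than assuming circularity.

Two decompositions are provided, because the literature on erosion-shell
analysis is split and the published descriptions of the method this
package operationalizes do not disambiguate:

* `equal_area` (default): shells are quantile bands of the
  distance-to-boundary transform, so every shell holds $\approx 1/S$ of
  the nuclear area. Under a uniformly random ("area-proportional")
  placement of signal, each shell expects exactly $1/S$ of the signal,
  which makes the chi-square null below particularly clean.
* `fixed_erosion`: the distance range is cut into $S$ equal-width bands
  (equal erosion depth relative to the maximal inscribed radius), the
  behaviour of classical erosion scripts. Shell areas then shrink toward
  the centre, and the random expectation is the shell-area fraction
  rather than $1/S$.

Both are exposed; neither is asserted to be "the" published variant.
Every downstream function takes the expected shell-area fractions
explicitly, so the choice is transparent to the statistics.

**Numerical choices.** Pixels with identical distance values at a
quantile boundary are assigned by stable ordering on (row, col). This
makes the decomposition fully deterministic and lets an independent
oracle replicate it pixel for pixel, at a small cost: a 90° image
rotation can permute tied pixels across a shell boundary. The profile of
a *uniform* signal is exactly rotation invariant in `equal_area` mode
(tied pixels carry equal weight), and any signal is exactly invariant in
`fixed_erosion` mode (a pure function of the distance transform); both
properties are tested. Shell areas in `equal_area` mode are equal to
within one pixel.

## Measurement and pooling

`measure_profile()` sums probe intensity per shell and normalizes to the
nuclear total. Options: subtraction of the modal background level
(clamped at zero) before summing, and division by the per-shell
counterstain fraction (renormalized) for workflows that normalize probe
signal by DAPI content; the default is raw proportions. Nuclei with zero
signal after subtraction are flagged empty and excluded from pooling.
`aggregate_profiles()` averages per-nucleus proportion vectors
unweighted, so a bright nucleus does not dominate the pooled profile.

## The chi-square construction and `pseudo_n`

Radial distributions are compared with chi-square tests on
*pseudo-counts*: the pooled mean proportions are multiplied by
`n_nuclei * pseudo_n_per_nucleus` rather than by the raw pixel sum,
because pixel counts scale with magnification and would inflate the test
arbitrarily. The statistic is linear in `pseudo_n` (a tested property),
so `pseudo_n` is an explicit sensitivity knob, not a nuisance constant:

* `chisq_vs_random()`: observed = mean proportions × total pseudo-count,
  expected = shell-area fractions × the same total,
  $X^2 = \sum (O-E)^2/E$ on $S-1$ degrees of freedom.
* `chisq_groups()`: a $2 \times S$ homogeneity table of per-group
  pseudo-counts, again $S-1$ degrees of freedom; shells with zero
  combined count are pooled with their inward neighbour (recorded in the
  result).

The test is *calibrated* — type-I error ≈ the nominal level — when
`pseudo_n` matches the number of independent signal units per nucleus:
if each nucleus contributes $k$ independently placed spots and
`pseudo_n = k`, the aggregate observed counts are genuinely multinomial.
The calibration studies in the test suite therefore simulate nuclei
whose signal is `pseudo_n = 100` unit spots drawn from the placement
model (75 nuclei per dataset, 1000 datasets), observing rejection rates
within [0.03, 0.07] at $\alpha = 0.05$ for both tests, and power above
0.95 against a strongly central alternative
(weights $(0, 0, 0.2, 0.3, 0.5)$) at 75 nuclei per group. With real
images the effective number of independent units per nucleus is unknown
(signal pixels are spatially correlated within territories), so reported
p-values should be read as conditional on the chosen counting unit — one
reason published p-values from this design cannot be reproduced exactly
without the original images and counting convention.

Bonferroni correction is multiplication by the family size, clamped at 1,
applied across the between-group tests of one run.

# The synthetic-imaging model

## What the generator emulates

*Interphase*: fields of non-overlapping nuclei rendered as ellipses with
low-order Fourier boundary ripple (eccentricity 0–0.4, mean radius 40 px
by default — a fibroblast-like nucleus at ~0.1 µm/px metadata scale,
which is arbitrary and configurable since the source imaging scale is
not specified). Probe signal is `territories_per_probe = 2` (diploid) ×
`spots_per_territory = 3` (emulating pooled triples of BAC clones used
to boost interphase signal) Gaussian spots per nucleus, placed by one of
three radial models: `uniform_area` (the random null), `shell_weights`
(arbitrary per-shell probabilities), or `beta_radial` (Beta-distributed
boundary-distance quantile). Territory membership is a labelling of
spots, not a spatial cluster: every spot is drawn independently from the
placement model, so the generating radial distribution is exact ground
truth for recovery tests. Imaging noise is a constant background,
additive Gaussian read noise and Gaussian blur.

*Metaphase*: rod-shaped chromosomes (length by size class, width 5 px,
random orientation, non-overlapping placement with bounded retries and a
3.5 px clearance so smoothing cannot bridge neighbours) for each of the
$2n/2$ chromosome types of a species karyotype, two copies each. A probe
renders one spot per copy of the chromosome type carrying its GGA label
— in a fused configuration that is a macrochromosome, with the fused
segment placed toward the distal end of the rod — and zero spots for
probes listed as failures. Probing the same label in both colours places
the two spots near opposite rod ends, emulating the orientation design
with one BAC near each chromosome end.

What the generator does **not** emulate: 3-D nuclei and focal sectioning,
optics (PSF shape, chromatic shift), photobleaching, intensity banding
along chromosomes, touching/bent chromosomes, and spatially clustered
territory signal. Passing tests therefore demonstrate the correctness of
the measurement and inference code under the stated statistical model,
not robustness to every real-world artefact.

## The species panel

The shipped panel (`build_species_panel()`, editable as YAML) encodes 22
avian species across 10 orders with their published diploid numbers and
fusion configurations: the three falcons share one pattern (panel micros
10, 12, 13, 14, 15, 17, 18, 19, 21, 23, 28 fused to macrochromosomes,
with 15+18+19 together on the GGA4 homolog and 23+28 together on the
GGA2 homolog); the budgerigar fuses 10, 11, 14 and additionally 12, 13,
17; the cockatiel and red-crowned parakeet fuse 10, 11, 14; all other
species retain the ancestral pattern of discrete microchromosomes.
GGA25 probes fail in the zebra finch, blackbird and canary. The probe
panel covers GGA10–28 except GGA16.

Hosts for fused micros other than the 15+18+19 → GGA4 and 23+28 → GGA2
assignments are not individually documented in the source material; the
panel assigns each remaining fused micro to its own distinct macro host,
which preserves every property the analysis measures (fusion partner
sets, carrier size class). Unprobed chromosome types (e.g. GGA16 and the
smallest unsequenced micros) are rendered as unlabelled filler so the
rendered object count equals $2n$. One enumeration subtlety is surfaced
rather than silently fixed: the fusion lists above leave six labels (20,
22, 24, 25, 26, 27) unfused everywhere, while the narrative convention
speaks of *five* conserved microchromosomes (22, 24, 25, 26, 27) —
GGA20's status is ambiguous in the source. The default panel follows the
enumerated fusion lists, so `conserved_set()` on the default panel
returns six labels including GGA20; tests assert that the five
uncontested labels are included.

# Metaphase calling and map construction

Per spread, `call_pair()` compares the sets of chromosome objects marked
by each probe (spot-in-mask membership, not distance thresholds — robust
on rods and free of a calibration constant the source material does not
provide): containment of one label set in the other ⇒ `same`
(evidence-consistent co-residence, tolerant of single-spot dropout), two
disjoint two-object sets ⇒ `different`, anything else ⇒ `no_call`.
Aggregation over spreads (`aggregate_calls()`) requires at least 5
informative spreads and an 80% majority — repository policy, since the
source scores pairs across spreads without numeric criteria.
`build_rearrangement_map()` treats `same` verdicts as graph edges;
connected components of size ≥ 2 are fusion groups; a `different`
verdict inside a component is recorded as a transitivity conflict and
resolved by discarding the conflicting edge with the weakest informative
support. A microchromosome is `fused` if it belongs to a fusion group or
its spots ride on a macro-class carrier, `intact_micro` if evidence
exists and its carrier is micro-class, `no_data` otherwise.
`conserved_set()` returns the labels intact in every species with data
(absence of data does not veto).

## Simulation scale

Rendering the complete all-vs-all design at image level (27 probe
labels → 351 pairs × 10 spreads × 22 species ≈ 77,000 rendered spreads)
is needlessly expensive for studying the *inference*: the image chain
(render → segment → detect → assign) is validated once per scene type,
and its failure modes — dropped spots and wrong assignments — are
well-described at the call level. `simulate_species_calls()` therefore
runs the panel design directly on ground-truth spot assignments with a
5% per-spot dropout and 2% per-spot mis-assignment noise model, while
the test suite separately verifies that image-level calling
(`render_metaphase_scene()` → `segment_chromosomes()` →
`detect_spots()` → `call_pair()`) agrees with ground truth on falcon
probe subsets and single spreads of several species. Under the default
panel, 10 spreads per pair and this noise model, the inferred maps equal
the generating configurations exactly for all 22 species (a tested
acceptance property).

# Parameter reference

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_shells` | 5 | shells 0 (peripheral) … 4 (central), chart convention |
| shell `mode` | `equal_area` | flat random expectation; `fixed_erosion` for erosion-script comparability |
| `pseudo_n_per_nucleus` | 100 | counting units per nucleus; match to per-nucleus signal granularity |
| `min_circularity` | 0.6 | $4\pi A/P^2$ cutoff admitting elliptical nuclei; perimeter uses the Cauchy–Crofton corrected crack length (a rasterized disc scores ≈ 1.0) |
| `min_area_px` (nuclei) | 200 | rejects debris at the default nucleus scale |
| `min_separation_px` | 5 | non-maximum suppression radius ≈ spot FWHM |
| `min_informative` | 5 | spreads needed before a pair verdict |
| `majority` | 0.8 | winning fraction of informative calls |
| `drop_rate` / `misassign_rate` | 0.05 / 0.02 | call-level noise model for panel simulation |

# Worked example

```{r example, fig.width = 6, fig.height = 4}
# a biased (central) placement versus the uniform null, 75 nuclei each
mask <- make_nucleus_mask(40, eccentricity = 0.3, seed = 2)
unfused <- aggregate_profiles(
  simulate_shell_profiles(mask, radial_placement("uniform_area"),
                          n_nuclei = 75, spots_per_nucleus = 100,
                          seed = 1), "unfused")
fused <- aggregate_profiles(
  simulate_shell_profiles(mask,
    radial_placement("shell_weights",
                     shell_weights = c(0.05, 0.1, 0.2, 0.3, 0.35)),
    n_nuclei = 75, spots_per_nucleus = 100, seed = 2), "fused")
plot_shell_profiles(list(unfused, fused), shade_groups = "fused")
chisq_vs_random(unfused)
chisq_groups(fused, unfused)
position_summary(fused)
```

```{r panel}
panel <- build_species_panel()
maps <- run_species_panel(panel["Peregrine falcon"], n_spreads = 10,
                          seed = 11)
maps[["Peregrine falcon"]]
```

# Known limitations

* 2-D only; the shell model assumes a single focal plane or projection.
* Touching nuclei are rejected, not split; dense fields lose nuclei to
  the area/circularity filter rather than recovering them by watershed.
* The chi-square p-values depend on the pseudo-count convention (above);
  cross-study comparison requires matching that convention.
* The equal-area/fixed-erosion and raw/DAPI-normalized choices are both
  supported precisely because the canonical variant is not documented;
  results should state which was used.
* Synthetic data exercise the stated statistical model only; see the
  generator's non-goals above.
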