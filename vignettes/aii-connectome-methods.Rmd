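---
title: "Methods: quantitative analysis of AII amacrine connectomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of AII amacrine connectomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiinet)
```

This vignette explains the models, conventions and design choices behind
`aiinet`: what each quantity means, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the package
had to make a call that the underlying measurement practice leaves open.

## The annotation data model

A disc-annotated connectome volume stores every cell as a stack of 2D
discs, one per ~80 nm section: the largest inscribed circle of the cell's
profile. Child structures — ribbon and conventional presynapses,
postsynaptic densities (PSDs), gap junctions, adherens junctions, and
non-synaptic "touches" — are annotated the same way, except the disc
records the profile's *Feret diameter* (maximum caliper width). Links tie
a presynapse to one or more PSDs (ribbon dyads and triads), and tie the
two sides of a gap junction, adherens junction, or touch together.

`aiinet` keeps this as five tidy tables (`meta`, `cells`, `structures`,
`discs`, `links`) bundled in an `annotation_db`. Referential integrity is
checked at construction and again at load; symmetric links are stored once
with the smaller structure id first, and all on-disk writes are ordered by
id with doubles serialised at 17 significant digits, so write → load is
bit-exact and repeated exports of one database are byte-identical.

## Geometry conventions

**Feret diameter.** A structure's Feret diameter is the maximum of
`2 * radius` over its slices. It is the one-number size used for
gap-junction statistics: one value per junction, not per slice.

**Contact area.** The annotation practice sums per-slice measures, but no
closed formula for "area" follows automatically from disc stacks. The
package defines

```
area = sum over slices of (Feret diameter x section thickness)
```

i.e. it treats the disc stack as a planar profile through the junction.
For a roughly circular junction sliced through its centre this chord sum
converges to the true disc area `(pi/4) d^2`; a per-slice `pi r^2` sum
would instead inflate the area of multi-slice structures roughly by the
ratio of junction diameter to section thickness. The generator uses the
same convention when slicing intended diameters into annotations, so
analysis round-trips are exact. Both linked annotations of a contact trace
the same membrane apposition; the resolved contact therefore takes the
*mean* of the two sides' areas and the *larger* of their Feret diameters.

**IPL depth.** Stratification depth is a normalized linear scale anchored
at the inner nuclear layer border (depth 0) and the ganglion cell layer
border (depth 25), mapped linearly from section index. The scale is
treated as normalized units, not micrometres. Somas and necks sit above
the IPL at negative depth; this is expected and preserved.

**Compartments.** The AII's depth-segregated compartments are fixed at
neck < 0 ≤ lobule < 10 ≤ waist < 15 ≤ arboreal, with the OFF/ON sublamina
border at depth 10 (the conventional 40% sublamina a/b border). These
thresholds are this package's convention, chosen to reproduce the
canonical AII zones; they are centralised in `assign_compartment()` and
depth profiles are computed in unit-width half-open bins spanning
`[-5, 30)` so that area is conserved exactly (the profile sum equals the
contact-area sum to 1e-9 relative).

## Mosaic statistics

Density is count over circular field area. Tile spacing uses the
square-measure convention `1/sqrt(density)`: at 841 cells/mm² this gives
34.5 µm, matching the reported ~34 µm spacing, whereas the hexagonal
convention would give 37 µm and was rejected. Nearest-neighbour statistics
exclude focal points within one nominal spacing of the field boundary
(guard zone), since their true nearest neighbour may lie outside the
volume. Voronoi jitter is the mean soma-to-tile-centroid offset over
*interior* tiles (tiles untouched by the bounding window and wholly inside
the circular field), divided by the tile spacing. Note that the measured
jitter statistic is smaller than the generative lattice displacement: the
tile centroid moves with its displaced seed, so a 10% lattice jitter SD
yields a measured Voronoi jitter of roughly 6%. The package reports the
measured statistic and leaves the generative displacement a free
generator parameter.

Coverage factor is the squared diameter-over-spacing ratio
`C = (d_arbor / spacing)^2`, and the predicted grid connectivity counts
square-lattice offsets `(dx, dy) != (0, 0)` with `dx^2 + dy^2 < C`
(strict overlap; tangency excluded). This is the one convention pair under
which the ideal coverage factor of 4 yields exactly 8 connected
neighbours; area-ratio readings with circular measure would give 4 or 20
instead and are rejected for that reason.

## Connectivity rules and the audit

The stereotyped AII contact rules are encoded as a declarative table
(`default_ruleset()`): each row names a partner class or class group, a
focal compartment, a contact kind, a direction, and a mode —
`permitted`, `forbidden`, or `required_on_encounter`. The validator
classifies every AII-involving, non-touch contact as proper (matches an
allowing rule and no forbidding rule), a violation, or unmatched, so that
`proper + violations + unmatched = classified` always holds. Contacts
with unclassifiable partners are excluded with a warning rather than
failed — real volumes contain orphan processes. "Encounter" is
operationalised as any touch or specialization between two structures;
`required_on_encounter` rules are audited per cell pair and compartment
over exactly that encounter set, reporting honoured vs declined counts.
The audit therefore measures encounter *coverage* and does not assert that
touch annotation is exhaustive.

## Statistics conventions

All SDs are sample SDs (n−1). This matters: the hypothetical-outlier
solver (`outlier_sds_to_reach_cv`) asks for the smallest integer `k` such
that appending `mean + k*sd` to a sample known only by `(n, mean, sd)`
raises the CV to a target; under the sample-SD convention the canonical
inputs `(5, 75.6, 3, target 0.28)` give `k = 20`, while the population
convention would give 22. The solver returns a bracketing certificate
(CV at `k` and at `k − 1`) alongside the answer.

The two-sample t test from summary statistics is the pooled-variance
(homoscedastic) Student's t, two-tailed. The Kolmogorov–Smirnov p-value
uses the asymptotic Kolmogorov distribution with Stephens' small-sample
correction, `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D` with
`ne = nm/(n+m)`; for `lambda < 1` the theta-function form of the
Kolmogorov CDF is used (the alternating series degenerates near zero, and
identical samples must give p = 1). This corrected-asymptotic choice
reproduces both degenerate-sample reference p-values the package documents
(`~5e-7` for 200-vs-7 all-or-none samples, and small-sample two-sided
comparisons generally). The test suite checks the asymptotic p against an
exhaustive permutation oracle for every `n + m <= 10`; the oracle uses
mid-p tie handling (half weight on permutations tying the observed D),
the standard correction for the discreteness of tiny enumerations —
under plain ≥-counting the asymptotic p can fall below half the
permutation p at `n = m = 3`, which says more about enumeration
granularity than about either statistic.

Gap-junction size statistics are per-junction Feret diameters binned at
25 nm, with cumulative frequencies normalized to 1. Printed-value
comparisons round CVs to 2 decimals and percent differences and folds to
integers, always alongside full precision. One documented discrepancy:
from the printed maxima (745 vs 592 nm) the max-diameter difference
computes to 26% (58% in area), not the prose's "20%/60%"; the package
reports computed values.

## Coupling weight convention

Homocellular (AII::AII) versus heterocellular (AII::CBb) coupling
strength is compared **per AII endpoint**: a homocellular junction couples
two AII cells and contributes its area to both, so the homocellular total
is doubled relative to raw area. Under this convention the documented
junction counts (525 vs 172) and diameter distributions
(267 ± 95 vs 238 ± 95 nm, areas quadratic in diameter) imply a ~7.5-fold
homocellular advantage, matching the ~7-fold figure the package's default
configuration targets; raw totals would give ~3.8. The choice is
implemented and documented in `weight_report()`. At the fixed sample sizes
the ratio estimator carries ~6% sampling SE, so seeded runs scatter
roughly between 7 and 8.5; the recovery test compares the pipeline's
measurement against the generator's planted ledger, which it must match
(and does) exactly.

## The synthetic connectome generator

The generator emulates the *annotation schema and summary statistics* of a
densely annotated retinal volume — not its biology. What it reproduces:

* the cell-class census (39 AII, 104 rod bipolar, ~200 ON and ~180 OFF
  cone bipolar cells including seven CBb7, TH1 axonal cells, AI and
  wide-field GABAergic amacrines, OFF ganglion cells) in a 0.243 mm
  circular field at 80 nm section thickness;
* the AII soma mosaic as a jittered square lattice (841 cells/mm²,
  displacement SD 10% of spacing) clipped to the field;
* compartment scaffolds per cell class: AII somas and necks above the
  IPL, six lobules within a 15 µm reach (half the intercell spacing, so
  lobules tile without redundancy), waist discs, and an arboreal ring
  spanning 70 µm — the ring is laid with eight evenly spaced rim discs so
  the realized convex-hull diameter equals the configured span;
* contact cohorts drawn only where the default rules permit them: rod
  bipolar ribbons onto arboreal AII dendrites, homocellular gap junctions
  at arboreal overlaps (n = 525, truncated-normal 267 ± 95 nm on
  [50, 800] nm), heterocellular coupling (n = 172, 238 ± 95 nm) with the
  CBb7 cohort making 1–3 ribbons *and* 2–7 gap junctions onto consistent
  partner AII cells, OFF cone bipolar lobule input (2–5 per AII),
  amacrine conventional input in both sublaminae, TH1 input at the neck,
  lobular outputs to OFF bipolar cells, GABAergic amacrines and ganglion
  cells (every OFF alpha ganglion cell encounter synapsing), AI adherens
  at the arboreal level, and non-synaptic ganglion-cell touches.

**Two regulated distributions at once.** Rod bipolar cells express a set
number of ribbons (~31 ± 3.9) while AII cells regulate their ribbon
*intake* (~75.6 ± 3) regardless of how many rod bipolar cells they happen
to overlap. These cannot both hold as independent draws, and the
variance structure is the scientific point: partner counts are
geometric, synapse totals are regulated. The generator draws per-RodBC
ribbon supplies and per-AII intake quotas, fills each quota from the
residual supply of rod bipolar cells within the AII's 60 µm rod-input
field, and sends leftover ribbons to wide-field GABAergic amacrines (the
other dyad partners). Both target distributions are then realised: rod
bipolar means recover 31, AII intakes recover 75.6 with SD ~3, and the
partner-count CV stays several-fold larger than the ribbon-count CV.

**Area calibrations.** ON amacrine input areas are rescaled (two
fixed-point passes over the quadratic diameter–area relation) so the
planted ON-amacrine : rod-ribbon area ratio equals the configured 8:1;
TH1 input is similarly calibrated to one third of the total coupling
area. Gap-junction diameters are *never* rescaled — their distributions
are study conditions.

**Slicing.** Intended Feret diameters become per-slice discs with a
circular chord profile over an odd number of slices, the central slice
carrying the full diameter. Round-trips are exact by construction:
`feret_diameter()` returns the intended diameter and `structure_area()`
the planted area, and both are recorded in the planted-truth ledger that
parameter-recovery tests compare against.

**Determinism.** A single master seed derives fixed per-stage child
seeds; identical configurations export byte-identical databases.

What the generator does **not** emulate: realistic dendritic morphology
(scaffolds are rings and scatters, not arbors), image-derived measurement
noise, partial annotation or tracing errors, vesicle densities, molecular
phenotyping signals, and any cell classes beyond those named in the
default census. Passing recovery tests therefore demonstrates that the
*pipeline* measures what was planted under the documented schema — not
that real tissue obeys the planted distributions.

## Problem sizes and runtime

The default study conditions produce ~590 cells, ~7,600 contacts,
~15,800 structures and ~83,000 disc annotations; a full
generate → resolve → audit → report run takes on the order of ten seconds
on one core, and the whole test suite (including ~1,000-instance
brute-force oracle sweeps for the geometric primitives and the exhaustive
KS permutation scan) about a minute. Oracle sweeps use small instances by
design: the properties checked (max/sum identities, hull areas,
group-by recounts, BFS distances) are size-independent.

## Known limitations

* Contact depth is a single area-weighted mean per contact; a junction
  genuinely spanning a compartment boundary is assigned wholly to one
  compartment.
* The validator's class groups cover the classes named in the default
  census; the rule table is user-extensible (`read_ruleset()` /
  `write_ruleset()`) but makes no claim to the full partner repertoire of
  a real volume.
* The mosaic generator cannot simultaneously match the reported lattice
  spacing, nearest-neighbour spread and Voronoi jitter with a single
  displacement parameter; jitter is exposed as the free parameter and the
  others are emergent.
* Hop distances ignore synaptic sign and direction by design (the hub
  question is anatomical proximity); signed-flow analyses would need the
  directed multigraph, which `build_graph()` preserves.
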