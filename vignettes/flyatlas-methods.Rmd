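---
title: "Methods: comparing blastoderm expression atlases across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing blastoderm expression atlases across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyatlas)
```

This vignette documents the models, conventions, and numerical choices
behind `flyatlas`: what each analysis computes, which parameters matter,
what the synthetic-data generator does and does not emulate, and where
design decisions were genuinely open.

## Data model

A **pointcloud** is one imaged embryo: per-nucleus 3D coordinates (µm),
per-gene fluorescence levels (arbitrary units, non-negative), and a
symmetric neighbor relation whose 3-cliques triangulate the blastoderm
surface. An **atlas** is a species-level average over many registered
embryos: per-cohort nucleus positions, a mean expression tensor
`E(i, g, t)` (nucleus × gene × cohort), an optional matching standard
deviation tensor, and injective nucleus correspondence maps between
consecutive cohorts. Registration of real embryos to a morphological
template is upstream of this package: we consume pointclouds that are
already registered and share an indexing (exactly what the synthetic
generator produces).

Developmental time is morphological, not chronological: six cohorts by
percent membrane invagination, with half-open bins
[0,4), [4,9), [9,26), [26,51), [51,76), [76,100]. Published stage ranges
overlap at 50%; we resolve 50% into cohort 4, which keeps the bins a
partition.

### Cylindrical coordinates

The AP axis is the first principal component of the nucleus cloud — a
rotation-invariant choice that needs no axis annotation. Two conventions
cannot be inferred from geometry alone and are carried as metadata:
the AP sign (an `anterior` vector; otherwise a fixed sign convention on
the loading) and the dorsoventral frame (a `dorsal` vector). `phi = 0`
sits at the dorsal midline and increases through left (+π/2), ventral
(±π) and right (−π/2), so unrolled maps read D, L, V, R from top to
bottom. `ap` is rescaled so the anterior-most nucleus is 0 and the
posterior-most is 1.

## Morphology

**Surface area** sums `½‖(B−A)×(C−A)‖` over the faces of the
neighbor-relation mesh — the surface through nucleus centers, not the
egg shell. Meshes with an edge on more than two faces are rejected with
the offending edges listed.

**Local density** counts nuclei within a 15 µm disk around each nucleus
and divides by π·15². Two conventions were open:

- *Disk metric.* We use the 3D Euclidean ball intersected with the
  surface nuclei rather than a geodesic disk. At 15 µm on an embryo of
  ~80–100 µm radius the chord/geodesic discrepancy is below 1%, far
  under the sampling noise of ~28 nuclei per disk.
- *Center counting.* The center nucleus counts toward its own disk
  (an isolated nucleus has density 1/(π·15²), not 0). This is
  configurable (`includeSelf`).

Density maps resample per-embryo local densities onto a regular
(ap × phi) grid by nearest-nucleus lookup (with the angular coordinate
wrapped), then average over the embryos of a cohort. The default grid is
100 × 16; tests use coarser grids, which is purely a resolution choice.

## Atlas building

Embryos of one cohort are combined as `E = mean`, `S = sample (n−1) sd`
per nucleus and gene after an affine intensity correction. The
correction model is `raw_e ≈ gain_e · consensus + offset_e` per embryo
and gene; since only the fitting target ("minimize expression variance")
is specified upstream, the estimator is ours: alternate (a) consensus =
per-nucleus mean of corrected embryos, (b) per-embryo ordinary least
squares of raw against consensus, for 5 iterations or a relative change
below 1e-8. The affine family leaves a scale/offset indeterminacy; we
fix it by constraining the mean gain over fitted embryos to 1.
Degenerate cases: a constant-expression embryo keeps gain 1 (offset =
mean difference, with a warning); non-positive fitted gains — a failed
embryo — are clamped to 1 with a warning rather than silently inverting
the sign. Whether the original corrections were per-gene or global per
embryo is unknowable from the description; we fit per gene per embryo,
which contains the global model as a special case.

The per-gene **quality metric** is the mean of `S` over nuclei, then
over cohorts: at n embryos with additive noise of sd σ it estimates σ
itself (our tests check a ratio of 1 within 10% at n = 8).

## Binary cell-type analysis

The on/off threshold is `mode(values) + sd(values)` over all nuclei of
one gene, cohort and species. Two conventions needed fixing:

- *Mode of near-continuous data.* If more than half of the values are
  exactly equal, that value is the mode; otherwise a 100-bin equal-width
  histogram over [min, max] is used, the mode being the center of the
  fullest bin with ties broken toward the lower bin. The histogram width
  makes the estimator deterministic and scale-equivariant.
- *Strictness and sd.* "On" means strictly greater than the threshold
  (so an all-identical gene calls everything off), and sd uses the
  sample (n−1) convention.

A consequence worth knowing: the mode+sd rule presumes the background
(off) population is the majority. If a gene is on in > 50% of nuclei,
the mode lands on the on level and everything is called off. The panel
genes' domains cover well under half the embryo each, so this regime is
not reached in practice; our sharp-boundary recovery test deliberately
places the boundary so that the on region is the minority.

Cell types are the on-subsets of the 9-gene panel; combinations below
0.1% of pooled nuclei are discarded (strictly below — a combination at
exactly 1/1000 survives). The filter pools across all species, cohorts
and nuclei, because the retained type universe is described genus-wide;
per-(species, cohort) filtering is available as an option. Proportions
are computed over *all* nuclei of a cohort and deliberately not
renormalised after filtering, so filtered mass is visible as a column
sum below 1. The hb channel question (mRNA vs protein) is a data
question, not a code one: cell-type analysis conventionally uses the
mRNA channel and expression-distance matching the protein channel;
both are just gene columns here, and the caller picks the panel.

## Expression distance scores

Expression is first scaled per gene and cohort so the maximum over
nuclei is 1 (all-zero gene-cohorts are left unscaled with a warning).
Each cell's profile concatenates all panel genes over all six cohorts,
following the cross-cohort correspondence maps from an anchor cohort;
`D` is the squared Euclidean distance between profiles — squared
precisely because it is additive over genes and time points.

Spatial correspondence scales each atlas to unit egg length and centers
on the center of mass; the spatial match is the nearest target nucleus
in that frame. The local search evaluates `D` exhaustively over the
k = 30 target nuclei nearest to the query's mapped position ("nearest"
is defined among target nuclei in the target frame — the neighborhood
must live where the candidates live). At the default nuclear density,
30 neighbors correspond to a search radius of roughly 3–4 cell
diameters, so shifts up to ~3–4% of egg length can be absorbed.
Coordinates default to the final cohort, where atlases are customarily
rendered; this is configurable.

The displacement estimate averages the 3D positions of the m = 10
candidates with smallest `D`, weighted by `1/(D + ε)` with ε = 1e-12;
candidates at exactly `D = 0` are averaged uniformly (the weighting is
otherwise undefined there). Displacements are reported in target-atlas
µm by default, or in shared scaled (egg-length) units with
`scaled = TRUE`. One caveat the identity test makes visible: when
several candidates tie at `D = 0` (common in synthetic data, whose
patterns depend on AP position only, making same-ring nuclei
profile-identical), the weighted location is their centroid, so a zero
displacement is *not* guaranteed even between identical atlases — only
zero distances are. Along the informative (AP) direction the median
displacement still recovers generated shifts to within a quarter of a
cell diameter.

## Time-point matching and the hourglass curve

Profiles of two species are aligned over the union of their retained
cell types (absent types contribute 0) and compared by plain (not
squared) Euclidean distance, per the upstream convention for this
analysis. The matching is the greedy monotone path: time point 1 maps
to time point 1; each subsequent reference time point takes the
admissible (non-backward) column with the minimum distance, ties broken
toward the earliest time point (preserving maximal future flexibility).
The per-step exhaustive scan *is* the algorithm — no dynamic programming
is intended — and several reference time points may share one target
time point. The hourglass curve averages all `choose(n, 2)` unordered
species-pair distances per cohort, with SEM = sd/√pairs.

## The synthetic-atlas generator

The generator defines the study conditions for all tests. Defaults:
five species with egg lengths 393.8/416.2/450.9/394.1/457.4 µm and
target nucleus counts 5974/5894/6115/5081/5535 (matching the measured
species averages), equatorial radius EL/5, a 9-gene panel (4 gap-like
genes as products of logistic boundary functions, 2 terminal-like
domains at the poles, 3 pair-rule-like genes as sums of 7 Gaussian
stripes), boundary widths sharpening over cohorts by factors
1.7 → 0.75, pair-rule amplitudes ramping up over time, species-level AP
domain shifts of 0/0.5/1/2/3% EL and temporal offsets of 0/0/1/1/2
cohorts growing with phylogenetic-like distance from the reference
species, per-embryo lognormal gains (sd(log) = 0.2), positive uniform
background offsets (0.01–0.05), and per-nucleus Gaussian noise with sd
2% of each gene's maximum (1% in recovery tests, matching the stated
recovery conditions). Offsets are drawn positive because fluorescence
backgrounds are positive; this also keeps expression non-negative
without clipping, which would otherwise bias gain estimation.

**Geometry.** Nuclei sit on an ellipsoid-of-revolution surface. Rather
than dart-throwing plus a Delaunay triangulation of the unrolled
surface, we place nuclei on latitude rings spaced along the meridian
arc at hexagonal-packing distance, with per-ring counts proportional to
circumference × target density and angular positions drawn through the
inverse CDF of the density field with small jitter; the mesh is a
deterministic ring-zipper triangulation plus pole fans. We chose this
over dart-throwing because it is simpler, exactly reproducible, hits
the target count exactly, and produces a mesh that is closed and
manifold by construction (the test suite checks Euler characteristic
V − E + F = 2); the packing statistics the analyses care about (mean
nearest-neighbor spacing within 10% of the hexagonal ideal for the
computed area, blue-noise-like jitter) are preserved. Furrow
depressions — a cephalic ring near ap ≈ 0.32 and a ventral band at
phi = π — modulate the density field, emulating the low-density regions
where the furrows will form.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: dorsoventral modulation of expression
(patterns are functions of AP only, making the angular coordinate
uninformative for matching), regulatory dynamics (patterns are drawn,
not simulated), nuclear shapes and gastrulation movements,
species-specific qualitative pattern differences (domains shift and
scale but never appear/disappear), and real registration error between
embryos (embryos share indexing by construction). Conclusions about the
*pipeline* — recovery of shifts, offsets and gains; correctness of the
combinatorics, matching and geometry — transfer; conclusions about
biology do not.

## Numerical choices and degenerate inputs

- All randomness flows from one integer seed; sub-seeds for geometry
  and noise are derived arithmetically and kept below 2³¹. The geometry
  sub-seed depends on the seed and the species' morphological
  parameters only, so two species with identical morphology share
  nucleus placements — which makes "zero shift, zero noise ⇒ identical
  atlases" hold exactly.
- Nearest-neighbor queries use a kd-tree (`RANN::nn2`, exact mode).
  Local-density disk counts grow the `k` cap geometrically until no
  disk saturates it.
- Collinear nucleus clouds (no definable AP axis), empty gene lists,
  empty cohorts, missing genes, non-manifold meshes and untrackable
  correspondence chains are errors, not warnings; all-zero gene-cohorts
  in normalisation and all-identical threshold inputs are warnings with
  a defined result.
- Pointcloud files store coordinates and expression to 6 decimal
  places; round-trips are exact at that precision.

## Problem sizes

Unit tests run species at 200–4,000 nuclei; geometry oracles and
parameter-recovery checks use full-scale embryos (6,000 nuclei), and the
acceptance script runs the five default species at their full Table-1
scale nucleus counts. These sizes were chosen so the complete suite
exercises the same regime as the real atlases while remaining quick to
run on a laptop.

## Known limitations

- The BDTNP-style reader is best-effort (whitespace table with a header
  line; x/y/z plus numeric gene columns) and is validated only against
  synthetic fixtures; the deposited files' exact schema may need column
  mapping by the user.
- The mode+sd threshold is undefined in spirit for genes on in a
  majority of nuclei (see above); real panel genes do not reach this
  regime, but a custom panel might.
- `estimateGainOffset` assumes embryos share nucleus indexing; real
  embryo-to-template registration is upstream and out of scope.
- The displacement field reports the AP component relative to the
  reference atlas's egg length; for species pairs with very different
  egg lengths the scaled-space option is the better-defined choice.
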