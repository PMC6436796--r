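---
title: "Methods: the collaborative distribution-modeling workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the collaborative distribution-modeling workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sdmflow models the workflow of a national expert-network mapping system:
a core modeling team curates occurrence data and fits distribution
models, while domain experts contribute accessible-area polygons, habitat
preferences, map corrections and credibility scores. This vignette is the
package's own account of the methods: what each stage assumes, which
knobs matter, and where genuinely open design points were settled.

## Occurrence curation

Records are standardized from Darwin-Core-style tables into a flat record
schema with a fresh permanent identifier per row; provenance columns
(source identifier, institution, collection, catalog number) are
preserved verbatim and are immutable thereafter. The **documentation
score** is the count of populated fields among eight documentation
fields (event date, elevation, locality, institution, collection code,
catalog number, recorder, source identifier). It decides spatial-dedup
winners, so it is deliberately simple and recomputable.

**Automated flags** are pure predicates of the record and optional
reference layers, evaluated by a configurable rule engine. The default
set covers the error classes expert curation targets: `MISSING_COORDS`,
`ZERO_COORDS`, `OUT_OF_REGION` (reference polygon), `COORD_SWAP`
(transposing lat/lon moves the point into the region while the original
is outside), `ELEV_MISMATCH` (|stated − DEM| > 500 m; 500 m tolerates
georeferencing-scale uncertainty on mountainous terrain while catching
unit and transcription errors), `DUPLICATE_EXACT` (identical provenance
tuple) and `FUTURE_DATE`. Manual flags (`SUSPECT_ID`, `GEOREF_ERROR`,
`OTHER`) are expert assertions. **Visibility** is a pure function of the
flags: a record is visible iff none of its flags is in the per-dataset
blocking set, so groups with sparse data can run laxer filters by
swapping the set.

**Spatial dedup** uses a 30-arc-second lattice (~1 km at the equator)
anchored at the floored bounding-box origin, with half-open cells for
deterministic binning. Within a cell the highest documentation score
wins; ties go to the earliest permanent identifier — the tie-break is not
dictated by the problem, so determinism decided it. The dedup flag is
recomputed from scratch on every call, which makes the operation
idempotent.

**Audit.** Edits are restricted to coordinates, taxon and manual flags.
Every edit appends one entry (old and new values serialized as JSON, so
doubles survive exactly); reverts replay a record's entries newest-first
and are themselves logged as compensating entries. The log is therefore
append-only while `revert` restores any past state byte-exactly — the
property the test suite fuzzes with random edit sequences.

## Geospatial primitives

There is no compiled geospatial stack underneath: rasters are numeric
matrices with an affine grid (row 1 = north, half-open square cells,
`NA` = nodata), read and written as ESRI ASCII grids — a plain-text
format that is diff-able, portable and sufficient at the package's
national, ~1-km working scale. Polygons are coordinate rings with
even-odd membership (GeoJSON semantics, holes included) or union
membership for buffer geometries; point-buffer outlines are geodesic
circles traced with 72 vertices (area error < 0.2%), and buffer areas of
overlapping disks are integrated on a fine grid. Distances and polygon
areas are geodesic (haversine / ellipsoidal via geosphere). Metric
accuracy of the degree-grid approximations degrades with latitude; the
intended envelope is low-latitude national extents.

## The modeling ladder

Method choice is a step function of the usable occurrence count: 1–2
records give a 10-km point buffer, 3–4 a convex hull, 5–9 a climate
envelope, 10 or more the presence-background model. The count bands
overlap in common verbal descriptions ("3–5 hull, 5–9 envelope"); n = 5
is assigned to the envelope here because the more informative,
statistically evaluated method should win whenever it is feasible. A
degenerate hull (collinear points) falls back to the buffer with a
warning rather than failing the species.

**Thinning** enforces a minimum pairwise distance by greedily removing
the point with the most too-close neighbours (ties broken by a seeded
draw). The distance is a user input: it should come from exploratory
analysis of sampling density and autocorrelation, which the package does
not automate.

**Accessible area (M).** Background sampling and prediction are confined
to M. When experts supply no polygon the fallback is a 200-km buffer
around the occurrences clipped to the study region — wide enough to
contain the reachable environment for most terrestrial vertebrates at
national scale, and explicitly a default, not a biological claim. Expert
polygons partially outside the grid are intersected with it.

**Background.** Default 10,000 points at valid cells inside M, sampled
without replacement at cell level (one point per cell centroid). When M
holds fewer valid cells the draw is capped with a warning;
`allow_replacement = TRUE` instead returns exactly n by sampling cells
with replacement, for callers that need a fixed size. Bias-surface mode
weights cells by a sampling-effort raster; target-group mode passes
through the occurrences of related, equally-surveyed taxa.

**The envelope model** scores a site on each variable as
`2·min(F, 1−F)`, where F is the tie-averaged fraction of presence values
below the site's value: 1 at the presence median, 0 at and beyond the
envelope limits; site suitability is the minimum across variables. A
variable constant across presences carries no envelope information and is
ignored with a warning rather than poisoning the minimum.

**The presence-background model** expands variables into linear,
quadratic, pairwise-product and two-sided hinge features (50 knots at
presence-value quantiles), scales them to the unit training range, and
fits an L1-penalized logistic contrast of presences against background
weighted 1:100 — the standard infinitely-weighted-background equivalence
to a maximum-entropy density fit. Per-class base penalties (linear 0.05,
quadratic 0.1, product 0.2, hinge 0.5) times the user's regularization
multiplier form the penalty vector; the solver is glmnet over a fixed
100-step lambda path, taking the smallest lambda. Output is the
complementary log-log transform `1 − exp(−e^H · raw)` of the normalized
exponential model (H = background entropy), bounded in [0, 1]. Bit-level
agreement with the reference Java implementation is a non-goal; the
functional form and penalty structure are the established equivalents.

## Evaluation and tuning

Spatial blocks come from rank-based median splits — longitude, then
latitude within each half (k = 4; k = 2 uses the longitude split alone).
Rank-based splitting keeps fold sizes within one of each other when
coordinates are distinct; heavy duplication (records snapped to shared
cell centers) triggers a best-effort split with a warning.

Folds partition **presences only**. Each fold trains on the full
background, and test AUC ranks held-out presences against the full
background — the convention of the standard presence-background
evaluation tools. The alternative (restricting the comparison to the
test block's own background) measures discrimination against the block's
local environment; because a block is small and environmentally
coherent, that comparison can collapse or invert even for the true
suitability surface, which makes it an artifact of the comparison set
rather than a property of the model. Training omission uses the
10th-percentile training threshold recomputed inside each fold.

Tuning evaluates every combination of regularization multipliers and
feature-class subsets and selects by: minimum mean test omission, then
maximum mean test AUC, then smaller multiplier, then fewer feature
classes. Omission leads because the workflow's published product is a
thresholded binary map; AUC refines among equals; parsimony settles the
rest deterministically.

## Thresholds, feedback, expert maps

The p-th percentile training-presence threshold is the **largest**
suitability value observed at a training presence such that at most p%
of training presences fall strictly below it; ties at the threshold
count as present. This guarantees realized training omission ≤ p% and
maximality (verified against a brute-force candidate scan in the tests),
and makes the binaries at 30/20/10/0 nested. The slider accepts any real
p in [0, 30], not only the four published steps.

Feedback edits apply in a fixed order: over-prediction polygons → 0,
then under-prediction polygons → 1, then the habitat veto → 0.
Under-polygons are explicit expert assertions of presence and survive
over-polygons; the land-cover constraint is an ecological veto and is
applied last. The order is a convention that had to be fixed and
documented — no ordering is canonical. The same habitat masking is
available both for model post-processing and for expert-drawn maps
(range polygon minus barriers, intersected with an elevation band and
habitat classes), and an expert map is always a subset of its rasterized
range polygon.

## Registry

Lifecycle: `under_development → pending_validation → validated`, with
`published_external` for third-party intake (peer-reviewed submissions
publish immediately; others await a methods review). Approval requires a
mean expert credibility score ≥ 3 on the 1–5 scale; the quorum defaults
to a single score but is configurable, since how many experts must weigh
in is a governance choice, not a statistical one. Reopening a validated
model (new hypotheses, taxonomy changes, substantially new data) starts
a new version with a cleared score sheet; every transition is logged.

Fact-sheet statistics serve conservation-status assessment: model area
(sum of presence-cell areas), extent of occurrence (geodesic area of the
convex hull of presence-cell centers; with fewer than three distinct
cells it degenerates to the summed cell area), area of occupancy
(occupied 2×2-km lattice cells × 4 km²), and the elevation range over
presence cells. EOO ≥ area always holds (a hull contains its points);
AOO carries no such relation to area and none is asserted.

## The synthetic-data module

`make_landscape` builds spatially autocorrelated fields by Gaussian-blur
smoothing of white noise (edge-renormalized separable kernel) on a
0.01-degree grid anchored at (−75, 0) — roughly 1-km cells near the
equator — plus a south-to-north ramp DEM (0–3000 m) and a land-cover
layer from quintiles of an extra smooth field. Blurred noise was chosen
over a full Gaussian-process simulation for desk-scale speed; it
reproduces the one property the workflow is sensitive to (smooth spatial
structure in the predictors).

`make_species` defines truth as a product of per-variable Gaussian
responses rescaled to a maximum of 1. The default niche (optima 0.7 and
0.3 on two variables, breadth 0.10 of the unit variable range) is
calibrated to be a *strong* niche in a checkable sense: evaluating the
**true** suitability surface itself under the same spatial-block
protocol gives held-out AUC ceilings of roughly 0.83–0.93 across
landscape seeds, so a competent model has real signal to recover, while
a substantially broader niche caps even the truth near chance-adjacent
levels and could not discriminate a good model from a poor one.

`sample_occurrences` draws clean records proportional to true
suitability (optionally times a bias surface), varies documentation
completeness so dedup has something to rank, and injects labelled
corruption — (0, 0) coordinates, transposed coordinates, exact
provenance duplicates, misidentifications placed on low-suitability
cells — at user-set rates (5% each in the end-to-end scenario, a
realistic aggregate error load for aggregated museum data). Ground-truth
labels live in an attribute outside the record schema, so the QC stage
cannot see them.

What passing on synthetic data does *not* show: real occurrence data
have taxonomic drift, spatially structured (not independent) errors,
correlated predictors with measurement error, and experts who disagree.
The synthetic scenarios validate the machinery and its guarantees, not
field performance.

## Problem sizes and numerical choices

The test suite runs landscapes of 25–100 cells per side, 10,000
background points, and 10-replicate recovery experiments — sizes chosen
so the full suite and the reproduction script each complete in a few
minutes on a single core while still exercising every code path at the
workflow's stated defaults. Degenerate inputs are handled explicitly:
single-point thinning returns the point; an empty presence set is an
error for thresholding and a warned all-zero result for distribution
statistics; an all-zero bias surface inside M is an error; grids must
match exactly unless nearest-neighbour resampling is requested. All
stochastic steps take explicit integer seeds, and the pipeline records
its seeds in model metadata.

## Known limitations

- Degree-grid metrics (cell areas, the ~1-km dedup lattice) assume
  low-latitude extents; high-latitude use would need a projected grid.
- The L1 presence-background model is a surrogate with the standard
  functional form, not a numerical clone of the reference
  implementation; per-class penalties are fixed rather than
  sample-size-interpolated.
- Spatial partitioning implements the block method only (k ∈ {2, 4});
  checkerboard and buffered leave-one-out schemes are out of scope.
- Polygon geometry supports rings and holes but not self-intersecting
  input; validity of user GeoJSON is assumed, not repaired.
- Thinning is greedy (near-maximal, deterministic per seed), not an
  exact maximum-independent-set solver.
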