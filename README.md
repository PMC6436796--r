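# sdmflow

An offline R toolkit for **expert-in-the-loop species distribution
modeling** at national scale. It implements the full collaborative
workflow used by expert-network mapping platforms: curate occurrence
records with a complete audit trail, pick a modeling method from the
number of usable records, fit and evaluate the model with spatial blocks,
convert it to binary range maps with percentile training-presence
thresholds, fold in expert feedback, and track every model through a
score-based validation lifecycle. A synthetic-landscape module generates
virtual species with known niches so the whole pipeline can be exercised
and benchmarked without any downloads.

## Who it is for

Modeling teams ("core teams") that turn messy occurrence tables plus
expert knowledge — accessible-area polygons, habitat preferences, map
corrections, credibility scores — into published, versioned range maps;
and anyone who wants a compact, fully testable presence-background
modeling stack in plain R.

## The method at its core

**Occurrence curation.** Records get permanent identifiers, preserved
provenance, and a documentation score (count of populated documentation
fields). Automated flags cover the standard error classes: missing/(0,0)
coordinates, points outside the study region, latitude–longitude
transposition candidates, elevation–DEM mismatch (> 500 m), exact
provenance duplicates, future dates. A per-dataset blocking set decides
visibility; within every 30-arc-second (~1 km) grid cell only the most
documented record stays visible. Expert edits are append-only logged and
fully revertible.

**The modeling ladder.** With `n` usable occurrences:

| n | method |
|---|--------|
| 1–2 | 10-km buffer around points |
| 3–4 | convex hull |
| 5–9 | climate envelope (per-variable percentile score `2·min(F, 1−F)`, site suitability = min over variables) |
| ≥ 10 | MaxEnt-style model: L1-penalized presence-background fit over linear/quadratic/product/hinge features, complementary log-log output in [0, 1] |

Background points (default 10,000) are drawn inside the accessible area
*M* (expert polygon, or a 200-km occurrence buffer as fallback) —
uniformly, from a bias surface, or as target-group occurrences.
Regularization and feature classes are tuned by k = 4 spatial-block
cross-validation: minimum mean test omission at the 10th-percentile
training threshold, ties broken by higher test AUC, then stronger
parsimony.

**Thresholds and feedback.** The p-th percentile training-presence
threshold is the largest suitability value omitting at most p% of
training presences (p ∈ [0, 30], the expert slider range); binaries at
30/20/10/0 are nested by construction. Expert polygon edits apply in a
fixed order — over-prediction → 0, under-prediction → 1, habitat veto →
0 — and expert-drawn range maps combine a range polygon with barriers, an
elevation band and habitat classes.

**Validation registry.** Models move through
`under_development → pending_validation → validated` (reopening makes a
new version); approval requires a mean expert credibility score ≥ 3 on
the 1–5 scale. Fact-sheet statistics follow IUCN range conventions: model
area, extent of occurrence (convex-hull area), area of occupancy
(occupied 2×2-km cells × 4 km²), elevation range.

Rasters are matrix-backed with plain-text ASCII-grid I/O; polygons are
GeoJSON in and out; everything stochastic takes an explicit seed.

## Worked example

```r
library(sdmflow)

stack   <- make_landscape(seed = 11, size = 60)          # env1, env2, dem, landcover
species <- make_species(stack)                           # known Gaussian niche
occ <- sample_occurrences(species, 120, dem = stack$layers$dem,
                          error_rates = list(zero_coords = 0.05, transposed = 0.05,
                                             duplicate = 0.05, off_range_misID = 0.05),
                          seed = 12)

region <- geo_polygon(cbind(c(-75, -74.4, -74.4, -75), c(0, 0, 0.6, 0.6)))
ds <- occ_standardize(occ)
ds <- occ_run_checks(ds, reference = list(region = region, dem = stack$layers$dem))
ds <- occ_dedupe(ds)
ds
#> <occ_dataset> 120 records (96 visible), 0 audit entries

vis  <- ds$records[ds$records$visible, ]
keep <- thin_points(vis$lon, vis$lat, min_distance_km = 2, seed = 13)
pts  <- vis[keep, c("lon", "lat")]
select_method(nrow(pts))
#> [1] "maxent_like"

M   <- accessible_area(species$M_true)
pts <- pts[point_in_polygon(M$geometry, pts$lon, pts$lat), ]
fit <- fit_final(pts, stack_subset(stack, c("env1", "env2")), M = M, seed = 14)
fit
#> <sdm_result> method maxent_like, 54 presences, binaries at [0, 10, 20, 30]
#>   mean spatial-block AUC 0.769

thr <- threshold_at_percentile(fit$suitability, pts, 10)
sprintf("threshold %.3f, training omission %.3f", thr$threshold, thr$omission)
#> [1] "threshold 0.502, training omission 0.093"

rec <- model_record("demo-1", "Virtualis exempli")
rec <- transition(rec, "feedback_processed")
rec <- add_scores(rec, c(4, 3, 5), reviewers = c("e1", "e2", "e3"))
rec <- transition(rec, "approved")       # mean 4 >= 3: validated
distribution_stats(thr$binary, dem = stack$layers$dem)[c("area_km2", "eoo_km2", "aoo_km2")]
#> area 801 km2, EOO 1353 km2, AOO 956 km2
```

The 120 raw records shrink to 96 visible ones after flagging and 1-km
dedup; thinning and the accessible-area screen leave 54 presences, so the
ladder picks the presence-background model. The 10th-percentile threshold
omits 9.3% of training presences (≤ 10% by construction), and the
validated model's fact-sheet statistics obey EOO ≥ area.

A consolidated command-line front (`inst/cli/sdmflow`) exposes the same
steps as `qc`, `synth`, `fit`, `post`, `registry summary` and `pipeline`
subcommands.

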