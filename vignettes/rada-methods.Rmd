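---
title: "Resource-Area-Dependence Analysis: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-Area-Dependence Analysis: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

RADA reads resource requirements off the *structure* of home-ranges. The
premise: animals in a heterogeneous landscape adjust range size, shape and
configuration so that each range encloses at least the minimum area `a_h`
of the map category carrying a required resource. An animal served by one
large patch holds a small range; an animal that must combine several small
patches holds a large one. Across a sample of I animals, the enclosed
category area is then approximately constant while range area `A` varies,
so the proportion `a/A` falls hyperbolically with `A`, and on natural logs

    ln(a_i/A_i) = b ln(A_i) + c

with `b = -1` and Pearson `r = -1` in the noise-free case. The x-axis
intercept (where `a = A`) gives `ln(a_h) = -c/b`, i.e. `a_h = exp(-c/b)`;
with `b = -1` this reduces to `exp(c)`. Individual variation in requirement,
patch quality, or mapping error flattens the slope (`b > -1`, `r > -1`) and
biases the intercept downward — which is why the package also reports the
geometric mean of the observed category areas and recommends it whenever
`b` differs significantly from −1 (t test on `(b+1)/SE(b)`, n−2 df; a
residual-free fit is treated as an exactly known slope).

Assumptions worth keeping in view: resource content is proportional to
category area within patches; the sample of animals is representative and
reasonably homogeneous (split age classes or strategies when not); and the
map's categories actually separate the resource (a category mixing rich and
poor habitat dilutes `b` toward 0).

## Why significance comes from randomization

`A` appears on both axes of the regression, so even unrelated landscapes
produce nonzero slopes and the parametric null of "no relationship" is
wrong. The package therefore builds an empirical null: 999 replicates, each
drawing I outlines *with replacement* from the observed set, rotating each
by U(0, 2π) about its area centroid, and displacing the centroid uniformly
(rejection sampling) within a convex study hull spanning all observed
outlines of the estimator at its most expansive core. Category areas are
recomputed for every placement and the regression refitted, so the null
distribution of `r` inherits both the artefactual dependence and the
landscape's spatial structure.

With 999 replicates a two-tailed observed value is banded by its distance
from the nearer edge of the replicate distribution: fewer than 50 beyond it
gives P < 0.10, fewer than 25 gives P < 0.05, fewer than 5 gives P < 0.01,
and none beyond gives P ≤ 0.002 for one run or P ≤ 0.001 when two
independent runs both leave nothing beyond. For other replicate counts the
package reports the generic two-tailed estimate `2(k+1)/(n_rand+1)`. A z
statistic against the replicate mean (normality assumed for `r`) is
reported with a 95% CL for the random mean.

Three design points the method leaves open, and the choices made here:

* **"Placed within the hull"** is read as *centroid* uniform in the hull;
  the alternative (whole outline inside the map extent) is available via
  `placement = "contained"`. The centroid rule keeps the placement
  distribution exactly uniform and is cheap; overhang beyond the mapped
  extent counts as background, consistent with treating unmapped land as
  resource-free.
* **Ranges lacking the category**: `omit` drops them from the fit (both
  observed and replicate fits); `beta` keeps them through
  `ln(β + a/A)` with β = 0.01 when the category's mean proportion exceeds
  0.10 and 0.001 otherwise, the rule evaluated on the current (possibly
  remainder-adjusted) composition; `resample_until_present` re-places an
  outline until the category is present, matching how sparse categories are
  commonly handled in randomization tables. Presence at the *first* throw
  is always tallied before any re-placement — it feeds the placement test.
* **First-throw placement test**: the observed number of ranges containing
  a category, out of I, is compared by an exact two-tailed binomial test
  against the mean first-throw presence probability of the null. Over- and
  under-inclusion both matter (avoidance is informative).

The replicate geometry runs in compiled code (Sutherland–Hodgman clipping
of patches against convex outline parts, batched over replicates, on R's
RNG so everything is reproducible from one seed). Concave outlines and
raster maps take an R path: rasters are counted by the pixel-center rule,
concave vector overlays by fine-grid quadrature (512 cells along the longer
side by default).

## Masking and stepwise removal

A category required in quantity (say woodland) can hide a smaller
requirement (wheat) because proportions sum to one. After the strongest
significant negative correlation identifies category *h*, subsequent steps
regress each remaining category on the remainder `-hA_i = A_i - a_h,i`,
excluding animals whose remainder is zero, and repeat until no significant
negative correlation is left. When two candidate categories correlate
within `tie_tol` (default 0.05 on r) the more prevalent one is taken first,
since it is the plausible masker. Each step's significance uses the same
random placements with the identified categories' areas subtracted from
every replicate range, mirroring the observed conditional regression.

## Which core, and which estimator

Requirements need not operate at the full range: a forager may need its
meadow inside an intermediate core and its hunting perches near the
center. Outlines are therefore estimated over a grid of core percentages
(default 30, 35, …, 100) and, for each identified category, the scan
statistic `a/|b|` is computed per core; the selected core maximizes it
(ties to the largest core; non-negative slopes skipped). The ratio embodies
the trade-off seen in practice: small cores under-sample `a_h` (small
intercept), very large cores dilute the relationship (|b| → 0 *and* the
intercept falls), and the peak marks the operational core.

Estimators implemented (codes follow field usage):

* `Xr`/`Xk` — peeled hulls: convex hull of the ⌈mn/100⌉ locations nearest
  the arithmetic-mean center (`Xr`) or the mode of a reference-bandwidth
  kernel surface (`Xk`); ties in distance break by input order. `Xr_100` is
  the outer MCP.
* `Kf`/`Koad` — kernel isopleths: bivariate Gaussian kernel on a grid
  (default 100×100, bounding box padded by max(10%, 3h)); the outline is
  the density contour enclosing m% of the grid mass. `Koad` rescales local
  bandwidths by inverse square-root of a pilot density (normalized by its
  geometric mean) and optimizes the pilot bandwidth by least-squares
  cross-validation; a flat LSCV objective (heavy duplication) falls back to
  the reference bandwidth `h = σ n^{-1/6}` with a warning. Contour areas
  are hole-corrected by even-odd nesting depth, though isopleths with
  interior holes are rare for unimodal smoothers.
* `Ejt` — bivariate-normal ellipse: sample mean and covariance scaled to
  the χ²₂ quantile of m/100, polygonized at 128 vertices (area error
  < 0.1%).
* `Cxs`/`Cxi`/`Cv` — nearest-neighbour cluster cores: seeded from the
  mutually closest triplet; each step either assigns the location with the
  smallest mean distance to an existing cluster's members or starts a new
  cluster when an unassigned pair is closer than every such joining
  distance; stops once m% of locations are assigned; ties break to the
  lowest location index. Clusters whose nearest members sit within 3 mean
  nearest-neighbour distances are then merged — without this, tight clumps
  fragment into arbitrary sub-clusters. `Cxs` hulls each cluster (≥3
  members), `Cxi` hulls all clustered locations together, and `Cv` clips
  hull edges longer than 3 mean nearest-neighbour distances re-entrantly
  through the nearest interior point. The exact cluster rules of the
  classic desktop implementations are not published in reproducible detail;
  these are documented stand-ins with the same intent, not claimed
  equivalents.

Exploring many estimators invites type-I errors; the defaults cap the set
at five and drop the significance gate to P < 0.01 whenever more than two
estimators are swept.

## Confidence limits

Geometric means are back-transformed t-intervals on logs. For the
regression intercept `a_min = exp(-c/b)`, no standard interval exists for
a ratio of estimated coefficients; the package uses the delta method on
`-c/b` with the OLS covariance of (c, b), then exponentiates. This is a
documented approximation: it is symmetric on the log scale and can be
optimistic when `b` is poorly determined — one more reason the geometric
mean takes over when `b` is shallow.

## The synthetic generator

`make_landscape()` places non-overlapping rectangular patches (lognormal
areas, uniform placement, ≥20 m spacing) of each category in a rectangular
extent — a deliberate simplification of patchy mosaics that keeps every
overlay exact. `make_constrained_population()` then builds ranges with a
*known* enclosed resource area: sub-rectangles of patches hold exactly
`a_h · exp(ε)`, `ε ~ N(0, σ_ln²)`, drawn from 1–3 patches, plus a
background-only rectangle for the extra area. With `contiguous = TRUE` the
range is a single rectangle (resource strip at a patch edge extended into
patch-free background), which convex-hull estimators can recover from
sampled locations; the default disjoint form emulates multi-patch ranges
for cluster-style analysis and for testing the overlay and randomization
machinery directly. `simulate_locations()` samples uniformly within an
outline, optionally thinning background points so resource patches carry
`(1+bias)` times the density.

Defaults mirror ordinary field studies: 30 locations per animal,
populations of I = 30, individual variation σ_ln = 0.2, extra areas
lognormal with median twice the requirement.

What the generator does *not* emulate: movement autocorrelation, curved or
fuzzy patch boundaries, classification error, resource gradients within
patches, and territorial exclusion between animals. Passing the synthetic
recovery suite therefore demonstrates that the estimators, overlays and
tests are correct and calibrated — not that any particular field data set
meets the model's assumptions.

For the core-size scan there is a separate composition-level generator,
`make_core_constrained_compositions()`: the constraint holds exactly at a
chosen core m\*, and away from it the enclosed area mixes geometrically
toward availability-proportional content `p·A` with weight
`1 − exp(−decay·|m−m*|/100)`. Under this model the fitted slope is `−w`
and the intercept `a_h · p^{(1−w)/w}`, so `a/|b|` peaks exactly at m\* for
background proportions p < 1/e — a closed-form target the scan must
recover. Generating this pattern through location geometry would entangle
the test with hull coverage noise; the composition-level route isolates the
scan itself.

## Numerical choices and degenerate inputs

* Areas are hectares, coordinates meters, logs natural, throughout.
* Raster zonal rule: a pixel counts iff its center lies inside the outline
  — unbiased and fast; boundary pixels may differ from other
  implementations at one-pixel scale.
* Fits need ≥3 usable ranges and positive variance on both axes (absolute
  tolerance 1e-12 on the centered sums of squares); failures are *flagged*
  (`defined = FALSE`) rather than raised, and flagged replicates are
  counted separately in null summaries.
* Zero remainders in stepwise removal are excluded per step (tolerance
  1e-9 ha), not globally.
* Replicate ranges on rasters whose category area is ≤3 pixels are
  reported as a rare-pixel fraction: sparse categories can manufacture
  spurious negative correlations in both observed and random fits, and a
  high fraction warns that the band may be biased.
* Polygon validity is gated (≥3 distinct vertices, finite coordinates,
  positive shoelace area after dropping duplicate vertices); degenerate
  rings are rejected with a message rather than repaired, since no
  computational-geometry engine is bundled.
* Sizes used by the shipped test-suite simulations: 50 seeded populations
  (I = 30, σ_ln = 0.2) for coverage of the geometric-mean CL; 50 seeded
  scans for core recovery within one grid step; 200 seeded trials of
  999 replicates each for type-I calibration of the P < 0.05 band. These
  run in well under a minute of compiled-geometry time and were chosen as
  the smallest sizes at which the binomial check bands (±3 SE) are
  meaningful.

## Known limitations

* Vector overlays are exact only for convex outline parts (all hull,
  ellipse and cluster-hull estimators); concave outlines (`Cv`, kernel
  contours) fall back to grid quadrature with resolution-limited error.
* Shapefile and GeoTIFF input are not supported; maps travel as GeoJSON or
  Esri ASCII grid (both plain text). Coordinates must already be planar
  meters — there is no reprojection.
* Kernel isopleth areas are grid-resolution limited; increase `grid_n` for
  small cores on large ranges.
* The delta-method CL for `exp(-c/b)` is approximate (above).
* The stepwise procedure tests categories marginally at each step; with
  many categories and small I, the prevalence tie-break is a heuristic,
  not an optimality guarantee.
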