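---
title: "Methods: plaque quantification and spatial clustering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plaque quantification and spatial clustering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqcluster)
```

## The scientific question

In amyloid-depositing mouse models, plaques present at a reference time
point can be labelled in vivo with a blood-brain-barrier-permeant
dense-core dye (the "MX" channel) that stays bound for months, while a
pan-amyloid antibody applied at sacrifice (the "AB" channel) labels all
deposits. A structure that is antibody positive but dense-core-label
negative is therefore a *new* plaque, deposited after the reference time
point. The question this package quantifies is whether new plaques deposit
preferentially **near pre-existing plaques** — i.e. whether plaque growth
proceeds partly by *clustering* of deposits rather than only by uniform
growth of single seeds.

The analysis chain is:

1. **Detection** — threshold each calibrated channel at the background mean
   plus nine background standard deviations; keep 8-connected components of
   at least 20 px.
2. **Classification** — pair dense cores with antibody plaques; flag *new*
   (no core), *new-in-vicinity* (centre-to-centre distance to the nearest
   pre-existing plaque strictly below 40 µm), *flower* clusters (two or more
   new plaques around one pre-existing plaque), *multicore* plaques (two or
   more clearly separate cores inside one antibody boundary, with their
   merged/separate fate read from a dense-core counterstain, "TR"), and
   *large* plaques (area above 300 µm²).
3. **Null model** — per image, place the same number of new plaques
   uniformly at random, 1,000 iterations, and record the chance proportion
   falling within the 40 µm vicinity.
4. **Inference** — per animal (the statistical unit), compare observed and
   chance proportions with a two-sided Wilcoxon matched-pairs signed-rank
   test; compare groups with Kruskal–Wallis plus Dunn's post hoc test, after
   a D'Agostino–Pearson normality gate; regress plaque area on core count.

No real images ship with the package: a synthetic-scene generator with
exact ground truth takes their place, and every stage is validated against
it.

## The synthetic scene generator

`scene_config()` / `generate_scene()` build a ground-truth scene;
`render_scene()` rasterises it into noisy intensity channels.

The default configuration emulates the post-mortem imaging regime the
pipeline targets:

| parameter | default | meaning |
|---|---|---|
| field | 688 × 512 µm at 0.43 µm/px | one cortical region of interest |
| `n_pre`, `n_new` | 12, 10 | plaques per field (tens per field) |
| `p_cluster` | 0.1 | fraction of new plaques deposited by the clustered mechanism |
| `cluster_radius_um` | 40 | vicinity radius |
| core radius | lognormal, median 3 µm, `sdlog` 0.3, floor 2.2 µm | dense-core size |
| `halo_radius_factor` | 4 | diffuse antibody halo radius / core radius |
| `multicore_p`, `extra_cores_mean` | 0.15, 0.3 | multicore plaques and their extra-core count (1 + Poisson) |
| `multicore_halo_growth` | 0.3 | relative halo enlargement per extra core |
| `separate_p` | 0.75 | probability multicore dense cores stay separate in the counterstain |
| `background_mean`, `background_sd`, `amplitude` | 100, 5, 150 | additive Gaussian noise and blob peak (30 × SD) |

Rationale for the values that are genuinely free choices:

* **`p_cluster = 0.1`.** With 12 pre-existing plaques the chance vicinity
  fraction of a typical layout is ≈ 0.14–0.15, so a 10 % clustered
  mechanism yields an expected observed vicinity fraction of ≈ 0.22–0.24
  among new plaques — the regime the analysis is designed to resolve. The
  helper `calibrate_p_cluster(target, chance)` inverts
  `t = p + (1 - p)·c` for other targets.
* **Core radius floor 2.2 µm.** At 0.43 µm/px a core below roughly 2 µm
  does not reach the 20 px minimum detection area at realistic peak
  intensities; the floor encodes that resolvability limit rather than
  pretending sub-resolution cores are measurable.
* **`halo_radius_factor = 4` and `multicore_halo_growth = 0.3`.** Diffuse
  halos are several-fold larger than their dense cores, and plaques
  assembled from several precursors are larger than single-seed plaques;
  the growth term plants the positive core-count-versus-size association
  that the regression stage measures.
* **Blob profile.** Isotropic Gaussian with σ = radius/2, truncated at 3σ.
  A simple, controllable profile whose suprathreshold disc has a
  closed-form radius σ·√(2·ln(peak/threshold)) — used throughout the tests
  to predict detected areas.
* **Noise.** Additive Gaussian only; Poisson shot noise is out of scope.

Clustered deposition is uniform on the disc of radius 40 µm around a
uniformly chosen pre-existing centre; draws landing outside the field are
redrawn (never clipped), so truth labels stay exact. A distance-decay
kernel was considered and rejected: the downstream category is a hard
40 µm rule, so a uniform-disc kernel matches the quantity being measured
and keeps `truth_vicinity_fraction` analytically predictable.

`min_separation_um` (default 0) optionally enforces a minimum
centre-to-centre distance by rejection. The default — unconstrained
placement — is the condition the spatial null model assumes; the separated
mode exists because *detector* fidelity is only well defined for resolvable
plaques (see "What the tests do and do not show").

Determinism: the same `(config, seed)` pair reproduces the scene and every
rendered pixel bit-for-bit; per-image streams in multi-image runs are
derived from a master seed and the image id by a 32-bit FNV-1a hash
(`derive_stream_seed()`), so results do not depend on processing order.

## Detection

The background model is the mean and SD of a plaque-free region. When no
region is supplied, a deterministic fallback tiles the image 8 × 8 and
takes the tile whose mean intensity sits at the 5th percentile of tile
means — dim enough to avoid plaques without chasing the single minimum,
which undershoots the noise floor. This replaces a manual plaque-free
region choice.

The threshold is `mean + 9·sd`. Adding the mean makes the 9-SD stringency
rule invariant to intensity offsets; both the multiplier and the additive
form are configurable. Components are 8-connected (the common ImageJ-like
convention; built as a 4-connected labelling plus a diagonal-merge pass),
filtered at ≥ 20 px, and sorted by descending area with a deterministic
tie-break on the first mask pixel in row-major order. `sd = 0` is an
explicit error — a degenerate threshold must not silently detect
everything.

The size-distribution variant (`detect_for_size_distribution()`) smooths
with a Gaussian kernel (σ = 1 px by default), subtracts the background
mean, clips at zero, applies the same noise-scaled threshold and keeps
components of ≥ 30 px (≈ 5.5 µm² at 0.43 µm/px). The smoothing kernel and
the reuse of the 9-SD rule for this variant are not externally fixed; both
are explicit configuration with the defaults above. Note the two area
conventions (20 px ≈ 5 µm² vs 30 px ≈ 5.5 µm²) imply slightly different
calibrations (0.5 vs 0.43 µm/px); pixel size is therefore always explicit
and defaults to 0.43.

Coordinates are 0-based, origin top-left, x = column; a pixel's centre is
at (index + 0.5)·pixel size. Centroids are unweighted mask centroids. An
optional border-exclusion margin discards components whose centroid lies
near an image edge — a deterministic stand-in for the manual removal of
section-edge artefacts.

## Classification

* A core belongs to the antibody plaque whose mask contains its centroid
  (full-mask containment is stricter than needed for partially overlapping
  cores and is not the default); cores outside every antibody mask are
  reported as orphans.
* *Pre-existing centre* = centroid of the plaque's largest core
  (distances are "core to core"); the antibody-mask centroid is a config
  alternative (`pre_center_method = "ab_centroid"`).
* Vicinity is a **strict** inequality at 40.0 µm.
* A new plaque within 40 µm of several pre-existing plaques counts once as
  in-vicinity (nearest-neighbour definition) but may appear in several
  flower clusters; its `flower_parent_id` is the nearest parent, and petal
  counts use unique petals.
* "Clearly separate" cores are distinct 8-connected components with no
  dilation merging.
* Core fate: a multicore plaque is *merged* when at least two of its core
  centroids fall inside one counterstain component, else *separate*;
  without the counterstain channel the fate is `not_applicable`.

## The random-placement null

Placements are uniform over the full field, with no exclusion zones and no
minimum separation — the literal random-location null (whether
plaque-occupied pixels should be excluded is a sensitivity question, not
the default). Points are dimensionless centres, consistent with
centre-to-centre distances. The per-iteration proportion is the fraction
of the `n_new` placed points within 40 µm of the nearest pre-existing
centre; the chance level is the mean over 1,000 iterations. For a fixed
layout this estimator is unbiased for the exact union-of-vicinity-discs
area (clipped to the field) over the field area, which
`chance_vicinity_fraction()` computes on a 0.25 µm grid as the
deterministic oracle.

Per-animal aggregation is a new-plaque-count-weighted mean over the
animal's images — every deposited plaque counts equally within an animal;
an unweighted mean is available. The Wilcoxon matched-pairs signed-rank
test is two-sided, drops zero differences (and reports how many), uses the
exact distribution up to 25 informative untied pairs, and the normal
approximation with continuity correction otherwise. All-zero differences
are reported as p = 1 with an explicit degeneracy flag rather than an
error. Fewer than 2 animals is an error; fewer than 6 a warning.

## Group statistics

The D'Agostino–Pearson omnibus K2 test (transformed skewness plus
transformed kurtosis, χ² with 2 df) gates the choice of test at
α = 0.05: the parametric route (one-way ANOVA + Tukey HSD) is taken only
when *every* sample passes; samples below n = 8 or constant samples force
the nonparametric route (tie-corrected Kruskal–Wallis, Dunn's post hoc
z-tests when the omnibus p < 0.05) with a warning. The gate is applied
programmatically and logged in the report, replacing unstated manual
routing. Dunn's multiplicity adjustment is Bonferroni over all pairs by
default (the convention of the usual commercial software), Holm by config.

An all-tied response degenerates the Kruskal–Wallis tie correction; this is
reported as H = 0, p = 1.

The statistical unit is the animal for group comparisons and the plaque for
the core-count-versus-size regression (ordinary least squares of area in
µm² on core count; slope, intercept, R², F-test p).

Summary proportions (fraction new, new-in-vicinity of new, flower petals of
new-in-vicinity, multicore of large, merged of multicore) are reported as
per-animal mean ± SEM per group and overall; animals with a zero
denominator are excluded from the mean and counted. Because the reported
values of the original study come from undeposited animal data, the package
reports these distributions rather than asserting any constant.

## Problem sizes used in the validation suite

The test suite validates properties at sizes chosen to give the binomial
or Monte Carlo resolution each claim needs: geometry against an O(n²)
oracle on 100 random configurations of up to 300 plaques; the analytic
chance level at 10⁵ iterations (3 Monte Carlo SEs); null calibration on
200 replicate studies of 20 animals × 10 images at 8 pre-existing and 8
new plaques per image with 1,000 iterations each; power at a 30 % clustered
fraction on 100 replicates; detection fidelity on 50 rendered scenes;
regression recovery on 100 datasets of 687 plaques; and the normality gate
and rank tests on 500 replicates (200 against a 999-permutation oracle).

## What the passing tests do and do not show

The generator emulates the *statistical structure* the pipeline assumes:
field geometry, plaque densities, lognormal core sizes, diffuse halos,
clustered deposition, multicore halos, additive noise. It does **not**
emulate vasculature or autofluorescent artefacts, uneven illumination, 3-D
stack effects, section-edge damage, or microglial reshaping of plaques —
so passing fidelity tests bound algorithmic error, not real-image error.
Two real-data effects do appear in the synthetic scenes and matter for
interpretation: overlapping halos physically merge at detection, which
*underestimates* the number of close new plaques exactly where clustering
is strongest (dense fields), and edge-clipped blobs shift centroids. The
fidelity benchmarks therefore run on scenes with a 35 µm minimum
separation and score interior plaques; the spatial-statistics benchmarks
run on unconstrained scenes at coordinate level, where truth is exact.

## Known limitations

* Analysis is per 2-D image; no longitudinal registration or tracking of
  plaque identity across sessions.
* The null is spatially homogeneous; layered-cortex intensity maps or
  pair-correlation analyses are natural extensions, not included.
* Mixed-effects modelling of image-within-animal nesting is out of scope;
  the per-animal aggregation is the unit of inference.
* The Kruskal–Wallis route relies on the χ² approximation at small group
  sizes; it is validated against a rank-permutation oracle in the suite.
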