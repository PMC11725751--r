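---
title: "Grouping pigs and grading farms from carcass weight and backfat"
author: "farmgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping pigs and grading farms from carcass weight and backfat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmgrade)
```

## The problem

Korean slaughter plants measure every pig's carcass weight (kg) and backfat
thickness (mm) to assign the meat-quantity grade: 1+ for 83 ≤ cw < 93 kg
and 17 ≤ bf < 25 mm, grade 1 for 80 ≤ cw < 98 kg and 15 ≤ bf < 28 mm
outside the 1+ rectangle, grade 2 otherwise; the final grade is the lower
of this and a separate quality grade. The grade prices the individual
carcass but says nothing about the *farm*: two farms with the same average
pig can ship very uniform or very scattered lots. `farmgrade` turns the two
grading measurements into (i) a pig grouping by deviation from the standard
pig, (ii) a Farm Management Grade summarizing shipment uniformity, and
(iii) per-group planes predicting primal-cut weights.

## The model

**Standardization.** Both traits are scaled by the absolute z-score
$|z| = |x - \mu|/\sigma$ with $\mu, \sigma$ the mean and *population* SD
(divisor $n$) of all pigs. At herd sizes in the tens of thousands the
$n$ vs $n-1$ choice moves abs z-scores by well under 0.01%; we use divisor
$n$ because the model standardizes with the moments of the very population
it was fitted on. Discarding the sign is deliberate: a pig 2 SD above and a
pig 2 SD below the mean are equally non-standard, and the clustering should
treat them alike.

**Clustering.** k-means with $k = 9$ on the $(|z_{cw}|, |z_{bf}|)$ pairs,
written from scratch because its details are the method: k-means++ seeding
(next initial centroid drawn with probability $D(x_i)^2 / \sum_j D(x_j)^2$),
Lloyd iterations, best of `n_init` independent restarts (default 200,
matching the original fit configuration; `max_iter` 1000). Numerical
choices the original description leaves open, fixed here once:

* *Convergence:* stop when the relative inertia change falls below
  `tol = 1e-6` (or inertia reaches 0).
* *Ties:* a point equidistant to two centroids goes to the lower cluster
  index; centroid-norm ties in relabeling break by the carcass-weight
  coordinate, then backfat. Both make the fit reproducible bit-for-bit.
* *Empty clusters:* an emptied cluster is re-seeded at the point farthest
  from its assigned centroid, which strictly decreases inertia and never
  stalls.
* *Seed:* a required, logged parameter (default 0); all randomness flows
  through it.

**Relabeling and groups.** Cluster numbers are not identifiable from the
optimization, so clusters are renumbered 1..9 by ascending centroid norm in
abs z-space — cluster 1 is the "least variation" cluster, and higher
numbers deviate more, which is the only labeling consistent with the
grouping's meaning. Groups are fixed: {1} → I, {2, 3} → II, {4, 5, 6} → III,
{7, 8, 9} → IV.

**Farm Management Grade.** A farm's grade is the group of its mean
(carcass weight, backfat), standardized with the *whole-population*
parameters stored in the model — never with farm-level moments, and the
model is never refit on farm means. Groups map I→A, II→B, III→C, IV→D.
Farms shipping fewer than `min_pigs` pigs are excluded. The default
threshold is 30; the threshold is reported inconsistently in the method's
original description (30 in one place, 25 in another), so the value is a
visible argument (`summarize_farms(..., min_pigs = )`) rather than a
constant.

**Primal-cut regressions.** Within each group, each of the five cut
weights is regressed on carcass weight and backfat,
$y = \beta_0 + \beta_1 cw + \beta_2 bf$, via QR least squares
(`stats::lm`). R² is the standard $1 - SSE/SST$ about the group mean and
MAE the mean absolute residual; both are in-sample, since no train/test
split is part of the method. Group comparisons use classical one-way
fixed-effects ANOVA with pooled-variance pairwise t-tests and Bonferroni
adjustment ($p \times \binom{k}{2}$, capped at 1), with compact
significance letters at $\alpha = 0.05$.

## The synthetic herd

The auction data the method was developed on (48,298 pigs, 94 farms over
two months) is not deposited, so the package carries a generator that
emulates its statistical structure:

* farm sizes from a Dirichlet-weighted multinomial
  (`farm_size_dispersion = 0.8`), every farm non-empty, some below the
  shipment threshold so the exclusion rule is exercised;
* per-farm mean shifts for both traits from zero-mean normals;
* (carcass weight, backfat) per pig from a bivariate normal around the
  shifted farm mean;
* cut weights on a configurable "true" plane in (cw, bf) plus Gaussian
  noise with $\sigma_c = \text{MAE}_c \sqrt{\pi/2}$, so the *expected
  absolute* error equals the configured MAE (half-normal mean identity);
* non-physical draws (cw ≤ 0, bf < 0, cut weight outside
  $[0, cw)$) are resampled, not clipped, to avoid probability atoms at the
  boundary.

**Calibration of the defaults.** Published summaries give the group means
(≈86.4 kg, ≈22.0 mm) and the *within-group* SDs, but not the
whole-population SDs or the trait correlation. The default marginal SDs
are derived once from the mixture-variance identity
$\sigma^2 = \sum_g w_g (\sigma_g^2 + (\mu_g - \mu)^2)$ using the four
group SDs (1.66/3.45/6.13/10.99 kg; 1.37/2.83/4.58/7.09 mm) and shares
(24.9/33.3/31.5/10.3%): ≈5.4 kg and ≈3.9 mm. These are split into a
within-farm part (5.0 kg, 3.6 mm) and farm-effect SDs (2.0 kg, 1.2 mm);
the correlation 0.30 is a typical carcass-weight–backfat phenotypic
correlation in finishing pigs. The true cut plane and noise MAEs default
to the bundled group IV regression rows — the group spanning the widest
carcass range, whose fits have the highest R² and therefore make the most
credible generating plane. None of these constants were revisited
afterwards.

**What the herd does and does not emulate.** It reproduces the bivariate
spread, farm structure and cut-weight error scale, and with it the
qualitative group structure: group IV comes out smallest and groups II and
III each larger, as published. It does not reproduce the published counts
exactly — group I's share runs a few points below the published 24.9%
because a symmetric bivariate normal is lighter near its center than the
real population — and the farm-grade distribution concentrates on A/B
rather than the published B/C, because real farm means scatter more
(management differences, breed, season) than symmetric zero-mean shifts.
Passing tests therefore demonstrate correctness of the *procedure* and its
qualitative behaviour, not numerical agreement with the undeposited data.
Seasonal effects, slaughter-date structure and the camera system's 52
carcass traits are out of scope.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle: the
grade classifier against an explicitly coded rectangle sweep over a dense
(cw, bf) grid; k-means against exhaustive enumeration of all assignments
on 12-point instances and against `stats::kmeans` (inertia within 0.1%) on
n ≤ 200 data; assignment against a brute-force nearest-centroid search;
ANOVA/Bonferroni against hand-computed pooled-variance formulas; and the
generator against its configured moments (3 SE at n = 50,000) and the
half-normal noise identity (2% at n = 200,000). Pipeline-level properties
— inertia monotonicity within every Lloyd run, partition invariance under
relabeling, recovery of the generating plane within 3 SE, the group-share
ordering and the rise of the group-IV share from farm grade A to D — run
on a calibrated 20,000-pig herd fitted with 50 restarts, a size at which
every group holds several hundred pigs and the checks complete in seconds.

## Known limitations

* Clustering is two-dimensional by design; the method inherits the
  grading system's restriction to carcass weight and backfat.
* k is fixed at 9; no model-selection (elbow/silhouette) machinery is
  included.
* The quality (2nd) grade is an input, never computed: only the
  lower-of-two combination rule is implemented.
* With n_init = 200 at the full 48,298-pig scale a fit takes a few
  minutes in pure R; `n_init` is exposed for users who want the original
  restart count rather than the quicker defaults used in the examples.
* Boundary handling of the grade bands assumes the printed half-open
  `low ≤ x < high` convention; how a mechanical grader treats exact
  boundary values is not documented anywhere authoritative.
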