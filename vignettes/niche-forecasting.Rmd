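---
title: "Methods: maximum-entropy niche models and climate-scenario range forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche models and climate-scenario range forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nichecast)
```

`nichecast` reconstructs, as reusable functions, a complete climate-envelope
ensemble forecast of the kind used to project habitat loss for montane
plethodontid salamanders: presence-only niche models contrasted against a
pooled target-group background, significance testing against null models,
dual-threshold binarization, projection onto future climate scenarios with
dispersal-buffer clipping, richness stacking, and a factorial analysis of
percent habitat loss. This vignette documents the model, the tunable
parameters, the synthetic data the package tests itself on, and the
numerical and design choices a user should know about.

## The maximum-entropy model

The core object is a Gibbs distribution over the background cells. Given
features $f_j(x) \in [0,1]$ of the climate covariates at cell $x$, the raw
output is

$$\mathrm{raw}(x) = \frac{e^{\sum_j \lambda_j f_j(x)}}{Z}, \qquad
  Z = \sum_{x \in \mathrm{background}} e^{\sum_j \lambda_j f_j(x)},$$

and the weights $\lambda$ maximize the penalized log-likelihood

$$\frac{1}{m}\sum_{i=1}^{m} \log \mathrm{raw}(x_i)
  \;-\; \sum_j \beta_j |\lambda_j|$$

over the $m$ presence records. Equivalently, the fitted distribution is the
minimum-relative-entropy distribution whose feature expectations match the
presence feature means to within the $\beta$-boxes; with every $\beta_j = 0$
the match is exact (this is asserted against a generic convex solver over
the probability simplex in the test suite).

**Features.** Five classes are available — linear, quadratic, product,
hinge (forward and reverse, knots at interior background quantiles) and
threshold — selected automatically by presence count the way the reference
implementation's "auto features" rule does: fewer than 10 presences use
linear only; 10–14 add quadratic; 15–79 add hinge; 80 or more add product
and threshold. All scaling constants and clamp ranges come from the model's
background; because presence records are added to the background by default
(`add_samples_to_background = TRUE`), the background here means the pooled
target group *plus* the samples, which keeps training-stack predictions at
background cells identical to the fitted distribution and guarantees the
moment constraints are feasible.

**Regularization.** Per-feature $\beta_j = \mu \cdot \beta_{\mathrm{class}}(m)
\cdot s_j / \sqrt{m}$, with $\beta_{\mathrm{class}}$ interpolated from the
published default tables (linear/quadratic/product from 1.0 at tiny samples
down to 0.05 at $m \ge 100$; hinge constant 0.5; threshold 2.0 down to 1.0),
$s_j$ the presence-sample standard deviation of the feature, and the global
multiplier $\mu$ (default 1.0) exposed for sensitivity analysis.

**Output scales.** The *cumulative* value of a cell is $100\times$ the raw
probability mass of background cells whose raw value does not exceed the
cell's own. Ties are inclusive: equal raw values share one cumulative value
and the top cell scores exactly 100. The *logistic* value is
$r e^{H}/(1 + r e^{H})$ with $H$ the entropy of the raw distribution; it is
0.5 everywhere for the uniform model, strictly increasing in raw, and the
three scales always rank cells identically.

## Evaluation: AUC and null models

Model discrimination is the presence-versus-background AUC in its
Mann–Whitney form (pairs where the presence outscores the background point;
ties count one half). It is invariant to the output scale. Significance is
judged against a null distribution built by drawing, without replacement,
presence-sized sets from the target-group pool and refitting the *identical*
pipeline; a species' model is significant when its AUC strictly exceeds the
empirical 95th percentile of the matched null distribution. The default
configuration mirrors the museum-record study the design comes from: a pool
capped at 4215 points, 1000 replicates, and null sizes 50/205/405/695. How a
species' presence count maps to one of those sizes is not specified in the
source design; this package uses the nearest size, resolving ties toward the
larger one, on the reasoning that a "representative" null should be at least
as flexible as the model it calibrates.

Two properties of this test are checked empirically in the acceptance suite:
its type-I error sits inside the exact-binomial 99% interval around 5% when
the "species" is itself drawn from the pool, and the null AUC mean decays
toward 0.5 from above as the null size grows (small presence sets overfit
upward).

## From surfaces to ranges, losses and richness

Binarization uses two rules. *Strict*: cumulative $\ge 10$ (the comparison
is inclusive; the source design states the cutoff without an equality
convention, and inclusive matches reference practice). *Liberal*: score at
or above the minimum training-presence score, applied on the raw scale —
any monotone scale gives the same range, which the suite asserts rather than
assumes. Whenever the minimum training presence falls below cumulative 10,
the liberal range nests the strict one.

Projected ranges (current and future alike) are clipped by the documented
range dilated by a fixed dispersal buffer — 10 km by default, great-circle
distance between cell centers via the haversine formula. The buffer is a
bookkeeping allowance for expansion, not a mechanistic dispersal model.
Percent habitat change is $100\,(A_{\mathrm{now}} - A_{\mathrm{future}}) /
A_{\mathrm{now}}$ on suitable-cell counts (gains are negative; the value
never exceeds 100). Area is an unweighted cell count on the fixed-cell-size
WGS84 grid; a cosine-latitude-weighted variant sits behind
`range_area(latitude_weighted = TRUE)` for sensitivity checks. Overlap with
the documented range is reported as the share of the *documented* range
captured by the model (the denominator is switchable, since the opposite
convention is also in circulation).

Richness maps are cell-wise sums of per-species binary ranges (species
complexes modeled as one unit count as one), and two richness surfaces are
compared by a two-sided paired *t*-test on their difference at points
sampled uniformly without replacement over the analysis frame (250 by
default). If every sampled difference is identical the *t* statistic is
undefined and the result carries a `degenerate` flag instead of a number.

## The factorial loss analysis

Per projection year, square-root-transformed percent loss is regressed on
GCM, CO₂ level and threshold (2-level factors, sum-to-zero contrasts) plus
current range size and range-centroid latitude (continuous, untransformed
and uncentered by default), with all main effects and all two- and
three-way interactions: 25 single-degree-of-freedom terms, so 35 units × 8
scenarios leave 254 error df. *F* tests use partial (Type III) sums of
squares (via `car::Anova`); sequential sums are available. Negative losses
(gains) are clamped to zero before the square root — the transform is
otherwise undefined — with the clamped count recorded on the result; a
signed-root alternative is exposed. The year enters as separate analyses,
not as a factor, matching the source design.

## The synthetic landscape and what it does (not) show

The generator exists so the pipeline can be tested where the truth is known.

* **Climate stacks**: layer-correlated Gaussian white noise (via the
  symmetric square root of a target correlation matrix, default
  $0.55^{|i-j|}$), smoothed by a separable Gaussian kernel
  (`autocorrelation_range` cells), standardized, and mapped to plausible
  units — temperature-like layers get a monotone north–south gradient
  (warmer southward, `gradient_strength` in SD units, default 1.5) and sit
  around 15 ± 4 units; precipitation-like layers around 1000 ± 300. The
  default stack has 11 layers (6 temperature-like, 5 precipitation-like) at
  0.0083° cells, emulating a winnowed bioclimatic variable set at ~1 km.
  The shared gradient raises realized temperature–temperature correlations
  above target; targets are matched exactly only for gradient-free layers.
* **Virtual species**: suitability is the logistic of a linear + quadratic
  predictor, so the truth is deterministic and bounded in [0, 1].
  `random_virtual_species()` draws unimodal niches with optima at interior
  climate quantiles and breadths of 0.35–0.8 layer SD on three active
  layers — range-restricted, montane-style species rather than ubiquitous
  generalists.
* **Sampling**: presences are multinomial draws proportional to true
  suitability times a bias surface (uniform by default; a collection-foci
  surface emulates museum-record bias), snapped to cell centers, with
  within-cell duplicates collapsed before fitting. Sets used for modelling
  must carry more than 30 records. The pooled, cell-deduplicated union of
  all species' points is the single target-group background every fit uses.
* **Known ranges**: the true range dilated onto coarse blocks (default 5
  cells) stands in for county-level distribution maps; it is a superset of
  the truth by construction.
* **Scenarios**: additive per-layer offsets; the default ensemble warms
  temperature layers and dries precipitation layers progressively across
  horizons, scaled per GCM and per emissions level so the ensemble brackets
  milder and harsher futures.

Passing recovery tests on these landscapes shows the pipeline is internally
consistent — an unbiased sample of a smooth, climate-determined species on
climate layers the model also sees is recovered with rank correlation
≥ 0.9, and pipeline percent loss under uniform warming tracks the analytic
loss within 10 points. It does *not* show robustness to what real data add:
non-climatic range limits, taxonomic error, spatially structured sampling
bias beyond the simple foci model, novel-climate extrapolation, or
disequilibrium with climate.

## Numerical choices

* Optimizer: cyclic coordinate descent, prox-Newton step per coordinate with
  soft-thresholding and a halving line search on the exact penalized
  objective; convergence when the per-sweep improvement drops below `tol`
  (default 1e-6). The sweep cap defaults to 2000: on strongly correlated
  quadratic/hinge features the tail of convergence routinely needs several
  hundred sweeps, and a lower cap truncates fits short of the optimum.
  Unpenalized diagnostic fits that must match moments to 1e-6 use a tighter
  `tol` and a higher cap.
* Tie integrity: rank statistics (AUC) are computed on the linear predictor
  re-evaluated from the final weights. Exponentiating underflows for
  strongly unsuitable cells and the optimizer's incrementally updated
  predictor carries accumulated rounding; both corrupt exact ties between
  cells with identical feature sums and measurably shift AUC.
* Clamping: when projecting onto novel climates, covariates are clamped to
  the training background range (on by default, switchable).
* Degenerate inputs: constant layers lose their quadratic/product features
  with a warning; all-zero sampling weights, empty point sets, empty current
  ranges, and grid mismatches are errors; a constant GLM response yields an
  all-zero ANOVA table rather than an error; a zero-variance richness
  difference returns a degenerate flag.
* Problem sizes: the test and acceptance studies run on 25–80 cell square
  grids with 3–8 species, pools of a few hundred to ~1700 cells, 100–200
  null replicates and 100–200 calibration trials — sizes chosen so the full
  statistical behavior (moment matching to 1e-6, type-I calibration within
  the exact binomial 99% band, recovery bounds) is exercised in minutes while
  remaining statistically meaningful. The full-study defaults (4215-point
  pool, 1000 replicates, null sizes 50–695, 250 comparison points, 10 km
  buffer) are the package defaults in `study_config()`.

## Known limitations

* No cross-validation or held-out AUC: a single training AUC per species,
  evaluated against the background, matching the source design.
* No categorical features; no jackknife variable importance or response
  curves.
* The buffer and clipping treat dispersal as a fixed allowance; no
  mechanistic movement, land cover, or biotic interactions.
* Rasters are exchanged as ESRI ASCII grids (plus CSV, a plain-text lambdas
  format and JSON manifests); there is no GeoTIFF reader/writer and no
  vector geometry.
* Species are treated as independent units; no shared-borrowing across
  species and no random effects in the loss GLM.
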