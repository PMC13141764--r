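---
title: "Boundary morphometrics and prognostic models for insular glioma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary morphometrics and prognostic models for insular glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioshape)
```

## The problem

WHO grade II–III insular gliomas meet the basal ganglia along a boundary
that is usually well defined on axial FLAIR imaging, and whose *shape*
carries biological information: tumors that spread along the natural
anatomy of the basal ganglia form a smooth curved interface, while rapidly
proliferating tumors compress it into a sharp, nearly straight margin. The
package quantifies that interface on a single user-selected axial slice of
a binary segmentation mask, classifies it as linear (L) or curved (C), and
carries the classification through the downstream cohort statistics:
univariate association with clinicopathological variables, and
subgroup-specific Cox risk scores with internal validation.

## Boundary geometry

### From mask to arc

The full tumor contour is traced with marching squares at the 0.5 level
(`extract_medial_boundary()`), after restriction to the largest 4-connected
foreground component. Because the marching-squares polyline is a one-pixel
staircase, outward normals are computed from wide-support tangents
(central differences spanning about 5 px of arc length); the medial arc is
the longest contiguous stretch of the contour whose outward normal lies
within half of `angular_window` (default 90°) of the user-supplied medial
direction. This is a deterministic, orientation-based analogue of manual
interface tracing: the part of the contour facing the basal ganglia is, by
construction, the part whose normal points toward them. Coordinates are
scaled to mm by the (possibly anisotropic) pixel spacing.

### Fractal dimension and the L/C rule

`box_counting_fd()` estimates the box-counting dimension as the OLS slope
of log N(ε) against log(1/ε). Two estimator choices matter:

* **Efficient cover.** At each box size the grid is slid over several
  random phases and the *minimum* occupied-box count is used. Plain
  single-grid counts carry a coarse-scale excess (boxes grazed by the
  curve) that biases the slope of short smooth curves down to ≈0.95;
  minimizing over grid phases approximates the covering number in the
  definition of box dimension and removes most of that bias.
* **Scale ladder.** Box sizes follow a geometric ladder of ratio √2 from
  1 px up to a quarter of the curve's pixel extent, requiring at least 4
  scales spanning an octave. The 1 px scale is included deliberately: it is
  where the digitization of a curved line genuinely carries more mass than
  an axis-aligned straight one.

The whole measurement is repeated four times with fresh seeded grid phases
and the replicate slopes are averaged, mirroring repeated semi-automatic
measurements whose mean is taken. The classification rule is applied
verbatim to the mean estimate: FD ≤ 1 is linear, FD > 1 is curved, with no
tolerance band.

On the packaged fixtures this estimator behaves as the classification
needs: a digitized straight segment measures just below 1, the Koch-4
polyline (digitized at its native scale, one pixel per smallest segment)
lands within ±0.06 of the similarity dimension log 4 / log 3 ≈ 1.2619, and
an undulating sinusoidal interface measures clearly above 1. One finding
is worth stating plainly: a *perfect circular arc* is a rectifiable smooth
curve with true box dimension 1, and a near-unbiased estimator duly
measures it marginally below 1, classifying it L. The geometric dichotomy
that the FD rule captures is therefore straight-and-smooth versus
curved-with-texture, not straight versus ideally circular; real curved
tumor interfaces are irregular, which is why the rule works in practice.
The package's curved reference fixture is accordingly the sinusoidal
interface rather than an ideal arc.

### Curvature descriptors

For curved boundaries, `estimate_curvature()` fits smoothing cubic splines
to x(s) and y(s) and evaluates the signed curvature
κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} at uniform arc-length positions.
Five descriptors summarize the profile:

| descriptor | definition | unit |
|---|---|---|
| total curvature | mean\|κ\| × L (the integral ∫\|κ\|ds extended over the full arc) | rad |
| maximum curvature | max \|κ\| | 1/mm |
| average curvature | arc-length-weighted mean \|κ\| | 1/mm |
| curvature variation | RMS of Δκ/Δs (signed κ) | 1/mm² |
| tortuosity | L / D (arc length over endpoint chord) | — |

Design notes:

* **Unsigned totals.** The integral of \|κ\| makes a convex arc integrate
  to its subtended angle (a semicircle gives π, a full convex contour 2π),
  which is both the natural sanity value and what a tracing plugin
  reports. The signed κ is kept only inside the curvature-variation
  derivative.
* **Average curvature.** The "½(k₁+k₂)" notation of surface principal
  curvatures has no direct planar analogue; the implemented quantity is
  the arc-length-weighted mean of \|κ\|, a flagged interpretation rather
  than a guess at intent.
* **Curvature variation.** dκ/ds is a function; it is summarized by its
  RMS, a single scale-aware scalar usable as a covariate and verifiable on
  clothoids (curves with dκ/ds constant).
* **Endpoints.** A natural smoothing spline forces second derivatives to
  zero at its ends, so open-curve profiles are evaluated on the interior
  \[2%, 98%\] of arc length; total curvature is then the mean times the
  full length. Closed curves are padded periodically by a quarter turn on
  each side instead and use no margin.
* **Smoothing default.** `spar = 0.6`, fixed by the rule that a circle
  with 0.2 mm Gaussian point jitter must recover its curvature 1/r within
  10%; exposed in `boundary_config()`.

## Cohort analysis

Marker calling (`call_marker_status()`) applies the inclusive assay
thresholds: IDH1 ≥ 30% immunoreactive cells, ATRX and TP53 ≥ 10% stained
nuclei, 1p/19q co-deletion ≥ 25% of probe signals, MGMT ≥ 10% methylation.
Continuous variables are dichotomized at fixed clinical cut-points (age
38 years, volume 20.17 cm³, Ki-67 10%), stored in `shape_dictionary()` and
overridable.

`odds_ratio()` computes the cross-product OR with the 95% Woolf interval.
Orientation is an explicit parameter, never inferred: the published
summary table is not consistent with a single reference coding (the age,
ATRX and TP53 rows match the row-swapped cross-product, the rest the rows
as printed), so `table1_counts()` declares a per-variable orientation. Two
rows merit flags: the epilepsy row's printed OR (1.21) does not match its
own counts under either orientation (the cross-product gives ≈1.12), so
it is excluded from reproduction checks; and the OGS row's Woolf interval
computes (0.35, 0.94) where the published table prints (0.35–0.95) — a
last-digit discrepancy that is recorded, not asserted. The chi-square test
defaults to no continuity correction (the published choice is unknown);
Yates correction is available as a flag.

Collinearity screening (`vif_screen()`) excludes a covariate only when
three conditions hold together: pairwise |Spearman ρ| > 0.7, that
correlation's p < 0.05, and VIF > 10; within a triggering pair the larger
VIF is dropped, recomputing after each removal.

## Survival models and validation

Cox models are fit by partial likelihood with Efron tie handling (the
published choice is unstated; Efron is the less biased default).
`stepwise_wald()` implements forward entry by the smallest Wald p
(default `p_enter` 0.05, ties broken by declared candidate order) with
backward pruning at `p_remove` 0.10 and a fully logged path.

A caution that the package's own simulations quantify: with one truly
prognostic covariate among four independent null candidates, the
family-wise probability that at least one null covariate enters at
p_enter = 0.05 is ≈ 1 − 0.95⁴ ≈ 18.5%, so the final model contains *only*
the true covariate in roughly 80% of replicates (the true covariate itself
is found essentially always). Stepwise selection at conventional
thresholds over-selects by construction; this is a property of the method,
not a defect of the implementation, and tightening `p_enter` trades it
against power.

The two published risk scores are shipped as explicit model objects
(`risk_model_L()`, `risk_model_C()`) with their coefficient vectors,
adverse-level coding maps (Ki-67 > 10%, epilepsy present, TP53 mutant,
1p/19q co-deleted, volume > 20.17 cm³, IDH1 mutant, age > 38 years,
tortuosity above the cohort median — the only dichotomizations named in
the source material; the map is overridable so alternative codings can be
tested). The points thresholds 23 and 41 and the published validation
metrics are carried as *metadata*: the points scheme behind them is not
recoverable from the published material (under the default nomogram-100
scheme the Risk_L points range makes 23 atypical, suggesting a different
scaling), and the patient-level data needed to re-derive them are not
public. `to_points()` implements the default nomogram-100 scheme;
`threshold_search()` maximizes the Mantel-Cox statistic over candidate
cuts subject to a 10% minimum group size — note that the selected
statistic is a maximum and therefore optimistic, which the threshold-search
simulations demonstrate.

Internal validation follows the standard two routes:

* `bootstrap_validate()` — Harrell's optimism correction with the whole
  modeling procedure refit on each resample;
* `crossvalidate()` — event-stratified k-fold (default 5) with held-out
  concordance, plus calibration at a horizon: predicted event
  probabilities from the fold model's Breslow baseline hazard are compared
  with a weighted local-linear smooth of inverse-censoring-weighted event
  indicators; ICI is the mean and E50 the median absolute difference. The
  calibration horizon defaults to 36 months (unstated in the source
  material; 3-year progression is a standard clinical landmark) and is
  configurable.

## The synthetic-data generator

No patient-level data are public, so `make_cohort()` generates cohorts
with the structure the analysis assumes: the shape label is drawn with
P(C) = 169/330, each covariate conditionally on shape from the published
cell proportions, and progression-free survival from a proportional-hazards
model with exponential baseline (rate 0.01/month) using the published
Risk_L or Risk_C coefficients as the generating truth, censored uniformly
on (0, 120) months. These defaults put the median PFS at a few dozen
months and the event fraction near one half, matching the reported
recurrence range. With `exact_margins = TRUE` every published 2×2 cell —
including the missing-value counts of the pathology variables — is
reproduced exactly by permuting assignments within each shape group.

What the generator deliberately does *not* emulate: the joint dependence
among covariates (they are conditionally independent given shape; the real
joint distribution is unknown), any non-exponential baseline hazard shape,
informative censoring, and MRI intensities or segmentation noise (masks
are exact region indicators sampled at pixel centers, without
anti-aliasing). Passing tests therefore demonstrate that the estimators
recover known structure of this family, not that the real cohort's
numbers are reproduced. `make_shape()` provides the geometric fixtures
(straight edge, arc, sinusoid, Koch, clothoid) with closed-form descriptor
values where they exist; everything is bit-reproducible from its seed.

## Problem sizes and numerical choices

The simulation-based checks use cohorts of n = 2000 (100 seeds) for
coefficient recovery, n = 1000 (100 replicates) for selection behavior,
n = 330 for pipeline runs (matching the published cohort size), 200
bootstrap replicates and 5 folds for validation; geometry fixtures are
rasterized at 96–256 px. These sizes put every Monte-Carlo standard error
well below the tolerance it is checked against. Degenerate inputs are
refused with typed errors (empty masks, arcs of fewer than 3 points,
zero-length curves, degenerate contingency margins, folds without events);
bootstrap resamples without events are skipped and counted rather than
imputed.

## Known limitations

* Slice selection is a user input: the package does not locate the
  standardized axial slice, segment tumors, or do any 3D geometry.
* The FD of ideally smooth arcs sits at the classification boundary by
  mathematical necessity (dimension 1); the L/C rule is informative for
  real, textured interfaces.
* The published points thresholds (23/41) cannot be re-derived and are
  carried as metadata only, as are the published validation metrics and
  median-PFS differences.
* Only the univariate association surface is reproduced; the multivariable
  logistic models of boundary shape in the source material's supplement
  are out of scope.
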