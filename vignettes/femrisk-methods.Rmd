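---
title: "Methods: DXA-based 2D finite-element hip fracture risk"
author: "femrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DXA-based 2D finite-element hip fracture risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femrisk)
```

## The problem

Osteoporotic hip fracture risk is screened clinically with the T-score, a
summary of areal bone mineral density (aBMD) from dual-energy X-ray
absorptiometry (DXA). The T-score carries no information about femur
geometry, which co-determines whether a sideways fall fractures the femoral
neck or the trochanteric region. This package implements a pipeline that
turns a segmented proximal-femur DXA image plus the routinely reported
per-region mean aBMD values into a patient-specific two-dimensional
finite-element (FE) model of a sideways fall, and summarises the result as a
Risk of Fracture score, RF^. At the cohort level it classifies patients
against pooled RF percentiles and ranks Hip Structural Analysis (HSA)
geometry variables by how much of the RF^ variance they explain.

## Gray-level to BMD calibration

DXA vendors report mean aBMD only inside three regions of interest (ROIs):
neck, trochanter, intertrochanter. A per-pixel aBMD map is recovered by
postulating a linear relation between pixel gray `g` and aBMD:

aBMD(g) = b + m g.

Per ROI, the intercept is anchored at a fraction `f` of the ROI mean aBMD
(the assumed minimum BMD in the region), and the slope follows from
requiring that the mean of the non-zero grays in the ROI maps exactly onto
the reported ROI mean. The three per-ROI lines are averaged into a single
patient-specific relation. `f = 0.20` is the default (the trial fraction
that validates best against 3D CT-based reference models); `0.10–0.30` are
accepted via `pipeline_config(calibration = list(fraction_f = ...))`.

Two conventions were genuinely open and are resolved as follows:

* the intercept is anchored at gray 0, the literal reading of "line
  intercept" (the alternative — anchoring at the minimum observed non-zero
  gray — changes `b` by `m * g_min`);
* pixels inside the femur but outside all three ROIs use the averaged line,
  since the goal is one patient-specific relation.

Mapped values are clamped below at zero (possible only with exotic
configurations); "non-zero pixel" means gray strictly greater than 0 after
background masking. Background must be encoded as exactly 0.

## Plate model and materials

The femur is modelled as a constant-thickness plate in plane stress. The
thickness matches a circular section of diameter `w` (the HSA neck width):
matching the area gives `t = pi w / 4`, matching the bending inertia about
the out-of-plane axis gives `t = 3 pi w / 16`. A constant-thickness
rectangle cannot satisfy both at once, so the package defaults to the mean
of the two and exposes both pure methods (`thickness.method`).

The mesh is a structured grid of square 4-node quadrilaterals aligned with
the image pixels and clipped to the segmentation mask (target element size
0.5 mm, the validated mesh density). Pixel alignment makes the
element-to-pixel association exact: each element inherits the aBMD of its
source pixel.

The density chain is: areal BMD (g/cm^2) divided by the plate thickness (in
cm) gives volumetric density; dividing by the ash fraction (default 0.6)
gives apparent density; the piecewise power law

E = 15010 rho^2.18 MPa for rho <= 0.28 g/cm^3, 6850 rho^1.49 MPa above

gives Young's modulus. Moduli are grouped into 35 equal-width bins over the
per-patient observed range (left-open intervals, edge ties to the lower
bin), each element receiving the median raw modulus of its bin — the usual
discrete-material idiom of bone FE. The bin span is per-patient because no
absolute modulus limits are prescribed. Poisson's ratio has no prescribed value
in this modelling tradition; a uniform 0.3 is used (standard for
homogenised bone), configurable. A 1 MPa modulus floor guards positive definiteness where the
mapped BMD is numerically zero.

## Sideways fall

The impact force comes from a single-degree-of-freedom spring-mass model of
the falling body: impact velocity `v = sqrt(2 g h H)` with fall-height
fraction `h = 0.51` of standing height, effective mass half of body mass,
contact stiffness `5e4 N/m`. These defaults are the standard
sideways-fall conventions of the biomechanics literature, and each is a
config key. For zero
damping the peak force is `v sqrt(k m_eff)`; for an underdamped system the
closed-form peak of the spring force is evaluated at
`t* = atan(sqrt(1 - z^2)/z)/wd`. The overdamped regime is rejected.

Boundary conditions: the femoral head is grounded through springs totalling
10000 N/mm split evenly over the head boundary nodes in both in-plane
directions (stiffness figures for this boundary condition are sometimes
quoted in the torque-like unit "Nmm", inconsistent with translational
springs; the value is read as N/mm total); the
distal cut is slaved to a pinned master node free only in rotation (a rigid
link multi-point constraint); the impact force is distributed over a
configurable lateral arc (default 0.35 of the full circle) of the
trochanteric boundary, inclined 30 degrees counter-clockwise from the
shaft-perpendicular axis. The shaft axis is fitted by PCA of the shaft
region; the image convention is head up, medial side left, and is
configurable for mirrored scans.

Elements are bilinear plane-stress quadrilaterals with 2x2 Gauss
quadrature; strains are evaluated at element centroids. Assembly exploits
the congruence of pixel-aligned elements (one unit stiffness scaled by
`E t` per element) and solves the reduced symmetric system by sparse
Cholesky. Verification: a patch test reproduces a uniform strain field to
1e-10 relative; a 100 x 10 mm cantilever at 0.5 mm matches the
shear-corrected beam closed form within 2% (measured ~0.3%); global
equilibrium (springs + hinge vs applied force) holds to 1e-8 relative on
every phantom solve.

## Risk of fracture

Per element, RF divides the prevailing principal strain by its material
limit. "Prevailing" is ambiguous in words; the default `max_ratio` rule
takes `max(e1+/et, |e3-|/ec)` (conservative, standard for this criterion
family), with `max_magnitude` (the larger-magnitude strain over its own
limit) selectable. The limits default to the widely used yield strains
0.73% (tension) and 1.04% (compression), the literature-derived values
usual for this criterion family; both are config keys.

RF^ is the maximum RF outside the head and trochanteric regions, which are
excluded because the grounding springs and the load patch pollute local
strains. In the phantom's label map the excluded trochanteric region is the
greater-trochanter bulge dilated by 2.5 mm so that the re-entrant corners
where the silhouette primitives join — artificial stress raisers adjacent
to the load patch — fall inside the exclusion. Ties resolve to the lowest
element id. The RF^ element is labelled intracapsular if it lies in the
neck region, extracapsular otherwise (a deliberate heuristic).

Cohort classification pools the per-element RF of all patients (excluded
elements included, since the rule speaks of the RF of the whole cohort) and
computes the 90th/98th/99.9th percentiles with linear interpolation between
order statistics (type-7 quantiles; the convention is not prescribed, so
the R default is used and documented). A patient is flagged at risk iff
RF^ exceeds the 99.9th percentile or reaches 1.

## HSA ranking

Collinearity among the 20 HSA variables is screened by iteratively removing
the highest-VIF variable until all VIFs are at or below 10 (the
conventional cutoff; configurable). Exhaustive subsets of
the retained variables are fitted as linear models of RF^; each model is
scored with `AIC = n ln(RSS/n) + 2(k + 2)` (intercept and error variance
counted); Akaike weights `exp(-Delta/2)` normalised over the enumeration
give each variable a cumulative weight — the ranking statistic. Plain AIC
is the default; small-sample AICc is
available (`stats.aicc`) and is the better-justified choice at n = 28.
Predictors are z-scored before enumeration (a conditioning aid; the ranking
is invariant to affine rescaling).

## The synthetic phantom

No real images ship with the package; every stage is exercised against a
parametric phantom with known ground truth. The silhouette is a union of
primitives (shaft rectangle, inclined neck capsule, head disc, greater
trochanter bulge) controlled by clinically meaningful parameters (neck-shaft
angle, neck width, hip axis length, head radius, shaft width). The true
aBMD field is a smooth regional profile; grays are synthesized through an
exact affine line whose intercept is a chosen fraction of the femur-mean
BMD, plus optional additive Gaussian noise truncated at zero (the simplest
stand-in for detector noise). Image
spacing defaults to 0.5 mm so the default mesh is pixel-aligned, which
keeps the oracle comparisons exact. An optional semicircular notch in the
superior mid-neck provides a stress concentrator with a known location.

Cohorts draw shape and density parameters from post-menopausal-typical
distributions (NSA ~ N(125, 5.5) deg, neck width ~ N(33, 3) mm, HAL ~
N(105, 6) mm, head radius ~ N(24, 2) mm, shaft width ~ N(30, 2.5) mm,
BMD level ~ N(0.80, 0.13) g/cm^2, height ~ N(1.61, 0.065) m, weight ~
N(66, 11) kg, all clipped to plausible ranges). T-scores derive from the
neck ROI mean against a young-adult reference of 0.849 +/- 0.111 g/cm^2.

The HSA table deserves its own note. Real HSA estimates of width, buckling
ratio (BR) and cross-sectional moment of inertia (CSMI) carry partly
independent information — collinearity screening of real tables typically
retains exactly those and discards the redundant derived columns (ED, CSA,
section modulus). The phantom emulates that structure with three
quasi-independent latents per region: the width; a cortical thickness
`1.65 sqrt(aBMD/0.85)` mm times a lognormal(0, 0.2) patient-region factor;
and a lognormal(0, 0.2) section shape factor on CSMI. The
intertrochanteric width carries its own flare factor (lognormal(0, 0.08)).
Per-variable measurement error follows the reported precision ordering of
HSA estimates: ~2% on direct lengths, ~4% on CSMI, ~10% on BR (the least
precise), and sub-percent on the internally consistent derived columns.
With this structure the screening retains about 11 of 20 variables, as real
tables do.

When an `effect_spec` is given, a synthetic risk response
`0.65 + 0.18 (sum beta_j z_j + noise)` over the named (measured) HSA columns
is recorded in the truth bundle; the default response noise SD of 1.155 on
the z scale makes the two-driver signal explain ~60% of the response
variance, the regime used by the parameter-recovery study below.

What the phantom does *not* emulate: DXA physics (beam hardening,
soft-tissue overlap, scatter), 3D anatomy and projection effects, scanner
ROI placement, and realistic cortical/trabecular texture. Tests passing on
phantoms therefore validate the computational chain — calibration algebra,
meshing, the solver, the risk extraction, the statistics — not the clinical
accuracy of the risk score on real scans.

## Problem sizes and numerical choices

The test-suite and acceptance studies use: 28-patient cohorts at 0.5 mm
spacing for the end-to-end determinism run (~19 000 elements per femur);
1 mm phantoms for unit-level FE checks; 50 cohorts of n = 28 at 1 mm for
the recovery study (ranking over the canonical non-collinear 11-variable
subset — per-replicate VIF paths at n = 28 with p = 20 are sample-noisy,
which is a property of small-cohort collinearity screening itself, not of
the generator). The recovery rate sits near the intrinsic ceiling of
exhaustive-AIC selection at this sample size: with eleven ideally
orthogonal predictors the two drivers rank top-2 in about 92% of
replicates, so the 90% requirement leaves little sampling slack by design.

Other numerical choices: binning edge ties go to the lower bin; RF^ ties to
the lowest element id; quantile type 7; the VIF removal tie-break is
alphabetical, making the filter invariant to column order; degenerate
phantom geometries (neck wider than the head, hip axis shorter than the
head radius) are rejected at construction; meshes with more than one
connected component are rejected with the component count.

## Known limitations

A 2D plate cannot separate cortical from trabecular bone (the projection
overlaps them), cannot represent out-of-plane buckling, and applies all
boundary conditions in the image plane; strain fields near the constrained
head, the load patch and the distal cut are not trustworthy, which is
exactly why RF^ excludes those regions. The impact model is quasi-static:
the dynamic peak force feeds a static linear solve. Cohort-level percentile
thresholds computed on phantoms are properties of the phantom population
and carry no clinical meaning.
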