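---
title: "Fusing electromechanical maps with MRI-derived LV surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing electromechanical maps with MRI-derived LV surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmfuse)
```

## The problem

Catheter-based electromechanical mapping (EMM) measures unipolar and bipolar
depolarization voltages (UV, BV, in mV) and a motion statistic, linear local
shortening (LLS, in %), at scattered points on the left-ventricular (LV)
endocardium, and is used to steer intramyocardial injections toward the
infarct border zone. Late-gadolinium-enhancement MRI (LGE-MRI) is the gold
standard for infarct extent, summarized per myocardial sector as infarct
transmurality (IT, the percentage of the wall cross-section occupied by
scar). The two modalities live in different coordinate frames at different
spatial resolutions. This package implements the full fusion chain: build a
triangulated end-diastolic endocardial surface from stacked short-axis
contours, register the EMM point cloud onto it rigidly, project IT onto the
surface, and relate the mapped electrical/mechanical parameters to IT with
ROC threshold sweeps and a random-intercept mixed model. A synthetic
infarcted-LV phantom generator provides ground-truthed data for validation.

## Surface construction

`build_endocardial_mesh()` resamples each end-diastolic endocardial polygon
to `points_per_ring` (default 80, matching the 80 circumferential bullseye
segments) equal-arclength vertices, aligns the angular origins of adjacent
rings by minimizing the summed inter-ring vertex distance over discrete
circular offsets (which prevents twisted stitching), stitches adjacent rings
with quadrilaterals split into triangles, and closes the apex with a fan to
the centroid of the most apical ring. The apex must exist as a vertex
because it is the pivot of every rotation in the registration chain. The
basal boundary is left open; containment queries (`is_inside_lv()`) close it
with a temporary fan cap, so points on the atrial side of the basal plane —
outflow-tract mapping points — are outside by construction. Point-to-surface
distances are exact minima over all triangles, computed in compiled code and
tested against an independent brute-force oracle at 1e-9.

Scalar projection (`project_scalar_field()`) uses a distance-weighted local
linear least-squares fit over the `k = 12` nearest samples, clamped to the
global sample range. This reproduces constants and exact sample hits, has
exact affine precision inside the sample hull (for an affine field the clamp
cannot bind there), never extrapolates beyond the observed value range, and
behaves like nearest-sample assignment far from the data. We chose it over
barycentric interpolation on a tetrahedralization because the samples lie on
a thin curved shell where 3-D Delaunay tessellations are degenerate.

## Registration

The chain mirrors clinical practice in three stages, all rigid:

1. **Frame swap** (`standard_axes_transform()`): a constant, data-independent
   rotation between the mapping system's frame and the MRI patient frame,
   looked up by convention name. The mapping vendor's frame is not publicly
   standardized, so this is configuration, not inference.
2. **Apex alignment** (`apex_align()`): translates the estimated EMM apex
   onto the mesh apex and rotates the estimated EMM long axis onto the mesh
   long axis by the minimal rotation, leaving roll about the long axis at
   zero. Plain PCA is *not* a usable axis estimator here: a basally
   truncated LV shell is about as wide as it is long, and catheter maps
   oversample the infarct, so the dominant moment direction can tilt tens of
   degrees. Instead the basal opening is found as the largest empty
   spherical cap in the directions from the cloud centroid to the points,
   and the axis is refined by algebraic (Coope) circle fits to projection
   slabs with a damped line fit through the slab centers — both steps are
   insensitive to sampling density.
3. **Rotation-constrained ICP** (`constrained_icp()`): iterates closest-foot-
   point matching with a least-squares rigid update (SVD/Kabsch) about the
   apex pivot. The *cumulative* Euler rotation since the ICP start is
   clamped componentwise to ±10° (sagittal) and ±20° (coronal, transverse);
   translation is unconstrained. Acceptance and convergence are judged on
   the RMS distance, because that is the quantity the SVD step minimizes;
   the default stopping tolerance is 0.01 mm, far below the millimetre error
   scale of interest. Two numerical details matter in practice: the update
   is the classic incremental step (fit current positions to their foot
   points), which keeps the monotone-convergence guarantee, and the step is
   extrapolated along its screw axis (scales 8/4/2/1, best kept) because
   tangential sliding along a smooth surface otherwise converges extremely
   slowly. When no step improves, rotations about the long axis are probed
   directly (±2.5°…±10°, still clamped) before terminating, since
   point-to-foot updates carry almost no torque about that axis.

`manual_adjust()` exposes the interactive 6-degree-of-freedom refinement as
a programmatic API and refuses any single rotation beyond 5°, the bound
reported for manual optimization. The registration error statistic is the
mean ± sample SD of the exact point-to-surface distances of included points.

`filter_points()` implements the two exclusion rules: registration mode
drops points outside the capped LV volume *and* farther than 5 mm from the
surface (keeping genuine contact points with noise); analysis mode
additionally drops points whose nearest vertex lies in the most basal 2
slices (configurable), where collagen-rich valvular-plane tissue is low
voltage without being infarcted.

## Transmurality, wall thickening, border zone

`segment_transmurality()` is area-based: myocardium (epi minus endo) and
scar-intersect-myocardium are rasterized at `pixel_spacing` (default
0.25 mm) and partitioned into 80 angular sectors about the end-diastolic
endocardial centroid; IT is 100·scar/myo per sector, missing where a sector
has no myocardial pixels. The angular origin is the +x axis proceeding
counterclockwise — the literature does not fix an origin for the 80-segment
map, so ours is declared, and rotation equivariance is property-tested.
Classification into the five IT areas is the half-open partition
{0}, (0,25], (25,50], (50,75], (75,100].

Wall thickening is the end-systolic minus end-diastolic wall thickness per
sector, with thickness measured as the radial epi-endo distance along rays
from the end-diastolic endocardial centroid (3 rays per sector, averaged);
it may be negative in dyskinetic regions.

The published border-zone algorithm is not described anywhere, so
`border_zone()` ships a declared minimal definition: vertices with
`lo < IT <= hi` (defaults 0 and 75 — infarcted but non-transmural),
restricted to connected components adjacent to the transmural core when one
exists. On a smooth radially decaying field this produces the expected
single closed ring around the core.

## ROC grids and the optimal operating point

`roc_grid()` sweeps 40 reference cutoffs (positives: `ref >= t`) against 40
predictor thresholds (test-positive: `pred <= t` by default; low voltage
indicates disease). The shipped ranges reproduce the standard sweep: IT
0–100 % (step 2.5), UV 0–25 mV (step 25/40), BV 0–12 mV (step 0.3), LLS
−32–48 % (step 2), WT −5–15 mm (step 0.5). Because 40 steps define 41 grid
lines, a convention is needed: reference cutoffs include the minimum
(`min + step·(0…39)`) and predictor thresholds include the maximum
(`min + step·(1…40)`); the operating points of interest (IT ≥ 5, IT ≥ 97.5,
UV ≈ 9.38 mV, BV 1.2 mV) all lie on these grids. AUC per cutoff is the
trapezoidal area with (0,0) and (1,1) anchors; the "highest sensitivity and
specificity" rule is operationalized as the Youden-J maximum at the best-AUC
cutoff, with ties broken toward the lower cutoff and lower threshold
(conservative for ≤-threshold positivity). Cutoffs with an empty class are
left missing. AUC agrees with a Mann–Whitney pairwise-concordance oracle to
within the grid discretization (0.02), which is also the bound under
strictly monotone predictor transforms.

## Variance explained by a mapped parameter

`mixed_model_r2()` fits Gaussian random-intercept models by maximum
likelihood (`lme4::lmer`, `REML = FALSE` so that null and full fits are
comparable — ML is required for the ratio below to be well defined across
models with different fixed effects):

$$R^2 = 1 - \frac{\sigma^2_{full} + \tau_{00,full}}
                 {\sigma^2_{null} + \tau_{00,null}}$$

with residual variance $\sigma^2$ within animals and random-intercept
variance $\tau_{00}$ between animals. Singular fits (between-animal variance
estimated at zero) proceed with $\tau_{00}=0$ and are flagged. The variance
components are tested against a direct two-parameter profile-likelihood
optimization independent of lme4.

## Linear local shortening

LLS for index point $i$ is the weighted relative change of its distances to
all other points from end diastole to maximal systole,
$100\sum_j w_{ij}(d^{ED}_{ij}-d^{ES}_{ij})/\sum_j w_{ij} d^{ED}_{ij}$,
positive for shortening. The vendor's exact neighbor weighting is
proprietary; the package declares a tent window on the end-diastolic
distance — full weight on 8–15 mm, linear ramps to zero at 4 and 25 mm —
which reproduces the documented emphasis band, and the function is isolated
so alternates can be swapped in. Two properties are independent of the
window and are what the tests rely on: uniform scaling by $s$ gives LLS
$= 100(1-s)$ exactly for every point, and LLS is invariant under joint rigid
motion of both phases. The ES phase is taken as given in the trajectory
input; phase detection is out of scope. Whether the denominator should use
ED or cycle-mean distances is not recoverable from public descriptions; ED
is declared here.

## The synthetic phantom

`phantom_spec()`/`generate_phantom()` build a truncated-ellipsoid LV:
endocardial semi-axes (25, 25, 60) mm by default, 10 mm wall, 20 short-axis
slices from the equatorial base to near the apex, matching a typical
porcine/clinical short-axis stack. A smooth IT field (cosine-tapered in
angle and in the apex-base coordinate, peak 95 % over a 120° arc reaching
65 % of the way to the base) is realized slice-wise as scar polygons whose
outer radius encloses exactly the IT fraction of the wall's cross-sectional
*area*, so the analytic bullseye (computed by angular quadrature of the same
field) is a genuine independent ground truth for the rasterized measurement.
End-systolic contours contract radially by
`contraction · (1 − it_coupling · IT/100)` (defaults 0.15 and 0.9): scar is
hypokinetic, which couples wall thickening and LLS to IT. EMM sampling is
triangle-area weighted with territory above 75 % IT oversampled 2:1
(catheter maps concentrate on the infarct), positions jittered by the
contact noise, and voltages follow a linear IT link with Gaussian noise —
healthy means 12/3 mV and dense-scar means 4/0.5 mV for UV/BV, chosen to
bracket the clinically reported low-voltage cutoffs (≈9.4 and 1.2 mV) so
threshold recovery operates mid-grid. About 150 points per map reflects
typical acquisitions. All draws are `seed`-deterministic down to output
bytes.

What the phantom does *not* emulate: papillary muscles and trabeculation,
breathing- and heart-rate-induced shape change between acquisitions
(residual error beyond the rigid model), microvascular obstruction, and
far-field voltage effects. Passing the recovery tests therefore shows the
algorithms are correct under the rigid, smooth-field model — not that the
3 mm in-vivo error budget is reproduced.

### Registration-recovery study conditions

The recovery experiments (in the test suite and `scripts/acceptance.R`) use
a mildly elliptical short axis, b = 18 vs a = 25 mm, and 0.5 mm contact
noise. Both choices are driven by identifiability, not convenience: on a
circular cross-section the endocardium is a surface of revolution and *no*
algorithm can recover rotation about the long axis from surface distances;
the roll information grows with the ellipticity (a − b), and profiling the
noisy distance objective directly shows its minimizer can sit several
degrees away from the true roll when the contact noise reaches 1 mm with
~150 points. With b = 18 mm and σ = 0.5 mm the exact-minimizer spread is
well inside the 2° recovery target the tests assert. Real LV short-axis
sections are modestly elliptical, so the condition is physiologically
reasonable rather than adversarial.

## Problem sizes and determinism

Default analyses use 20-slice stacks meshed at 80 vertices per ring
(1601 vertices, 3120 triangles), ~150 EMM points per map, 20-phantom
recovery studies, and a 17-animal ROC/R² study of ~90 analysis points per
animal — the scale of a realistic preclinical dataset, which also keeps the
whole validation suite comfortably fast on a single core. Every stochastic
step takes an explicit seed; reports embed a configuration hash and are
byte-stable across reruns.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(endo_axes = c(25, 18, 60), seed = 1)
ph <- generate_phantom(spec)
samp <- sample_emm(ph)

# plant a mis-registration and recover it
truth <- rigid_transform(c(5, -8, 4), c(2, 2, 2),
                         pivot = ph$mesh$vertices[ph$mesh$apex_vertex, ])
emm <- perturb_rigid(samp$emm, truth)
reg <- register_emm(emm, ph$mesh)
reg$error

# relate UV to transmurality
it_grid <- transmurality_bullseye(ph$stack)
mesh <- project_it_bullseye(ph$mesh, ph$stack, it_grid)
pairs <- pair_points_with_reference(filter_points(reg$emm, mesh, "analysis"), mesh)
g <- roc_grid(data.frame(pred = pairs$uv, ref = pairs$ref),
              pred_range = emm_roc_ranges()$uv, ref_range = emm_roc_ranges()$it)
glance(g)
autoplot(g)
```

## Known limitations

* The registration model is strictly rigid; end-diastolic volume mismatch
  between acquisitions is reported through the error statistic, never
  corrected by scaling.
* The frame-swap table must be configured per acquisition setup; there is no
  way to infer it from data within this package.
* The border-zone rule and the LLS neighbor weighting are declared
  surrogates for unpublished vendor algorithms; both are isolated behind
  single functions for replacement.
* `segment_transmurality()` assumes star-shaped contours about the
  endocardial centroid for its polar partition (true of LV short-axis
  anatomy, not of arbitrary polygons).
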