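# emmfuse

Fusion of catheter-based electromechanical maps (EMM) with MRI-derived
left-ventricular endocardial surfaces, for researchers working on
image-guided intramyocardial injection and infarct characterization.

EMM systems (NOGA-style) record unipolar and bipolar depolarization
voltages (UV, BV, mV) and linear local shortening (LLS, %) at scattered
endocardial points, and are used to steer injections toward the infarct
border zone. Late-gadolinium-enhancement MRI measures infarct transmurality
(IT, % of the wall cross-sectional area occupied by scar). `emmfuse`
implements the full analysis chain that links the two:

* **Surface construction** — a triangulated end-diastolic endocardial mesh
  from stacked short-axis contours, with exact point-to-surface distance
  queries and an inside/outside test that excludes outflow-tract points.
* **Rigid registration** — constant frame swap, apex-based initialization,
  and an iterative-closest-point refinement whose cumulative rotation is
  clamped to ±10°/±20°/±20° about the sagittal/coronal/transverse axes at
  the apex pivot, plus a bounded (≤5°) programmatic manual adjustment. The
  registration error is the mean ± SD of the closest point-to-surface
  distances.
* **Transmurality mapping** — area-based IT per 80 circumferential segments
  per slice from rasterized scar contours, wall thickening from cine
  contours, the five-class IT partition ({0}, (0,25], (25,50], (50,75],
  (75,100]), a border-zone mask, and bullseye CSV export.
* **Statistics** — 40×40 ROC grids over reference cutoffs and predictor
  thresholds (UV step 25/40 mV, BV 0.3 mV, LLS 2 %, WT 0.5 mm, IT 2.5 %)
  with per-cutoff AUC and a Youden-J operating point, and the
  random-intercept mixed-model variance explained
  `R² = 1 − (σ²_full + τ00_full)/(σ²_null + τ00_null)` fitted by ML.
* **A synthetic phantom** — a truncated-ellipsoid LV with a smooth IT
  field, IT-linked voltages and motion, inhomogeneous point density, and
  known rigid mis-registrations, used as ground truth throughout the tests.

Tabular data flow as tibbles (pipe-friendly); results have `tidy()`,
`glance()` and `autoplot()` methods; meshes and rigid transforms are light
S3 objects.

## Worked example

Generate a phantom with a known mis-registration, recover it, and relate UV
to transmurality:

```r
library(emmfuse)

spec <- phantom_spec(endo_axes = c(25, 18, 60), seed = 1)
ph   <- generate_phantom(spec)
samp <- sample_emm(ph)

truth <- rigid_transform(c(5, -8, 4), c(2, 2, 2),
                         pivot = ph$mesh$vertices[ph$mesh$apex_vertex, ])
emm <- perturb_rigid(samp$emm, truth)
reg <- register_emm(emm, ph$mesh)
reg$error
#> <error_stats> 0.87 +/- 0.63 mm (n = 145, excluded = 5)
reg$transform
#> <rigid_transform>
#>   euler (sag, cor, trans) deg:   -5.243    7.344   -5.532
#>   translation mm:                -2.008   -1.731   -1.186
#>   pivot mm:                      -0.000   -0.000  -58.200
```

The planted perturbation was (+5°, −8°, +4°) with a (2, 2, 2) mm shift; the
recovered net transform is its inverse to within the 1 mm contact-noise
budget, and the residual surface error (0.87 mm) sits at the noise floor.

```r
it_grid <- transmurality_bullseye(ph$stack)
mesh    <- project_it_bullseye(ph$mesh, ph$stack, it_grid)
pairs   <- pair_points_with_reference(filter_points(reg$emm, mesh, "analysis"), mesh)
g <- roc_grid(data.frame(pred = pairs$uv, ref = pairs$ref),
              pred_range = emm_roc_ranges()$uv, ref_range = emm_roc_ranges()$it)
g
#> <roc_grid> 134 pairs, 40 x 40 grid
#>   best: ref >= 85, pred <= 5.62, AUC 0.996 (sens 1.00, spec 0.99)
```

A UV threshold of ≤5.62 mV best separates dense scar (IT ≥ 85 %) in this
noise-free-link phantom; `autoplot(g)` draws the ROC curve with the
operating point, and `plot_bullseye(it_grid)` the polar IT map.

A command-line front end wrapping the same functions ships in
`inst/cli/emmfuse.R` with subcommands `simulate`, `register`,
`transmurality`, `lls`, `roc`, `r2` and `report`; `report` runs the whole
pipeline on one dataset and writes a deterministic JSON summary.

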