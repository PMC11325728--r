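---
title: "Spatiotemporal registration and growth modeling of field TLS time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal registration and growth modeling of field TLS time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tls4d)
```

## The problem

Terrestrial laser scanning (TLS) of a breeding field produces one dense 3D
point cloud per survey session. Trait tracking over a season — canopy
height (CH), projected canopy area (CA), canopy volume (CV = CA·CH) per
plot — requires all sessions to share one spatial frame ("4D
registration") and one height reference. Plants change shape between
surveys, so the registration must lean on what is stable: the terrain and
the row/plot arrangement of the crop. tls4d implements that idea as a
two-phase pipeline, with a synthetic-field simulator supplying ground
truth so every stage can be validated without field data.

## Per-session conditioning

Each session cloud is denoised with a statistical outlier removal (SOR)
filter (mean distance to the 20 nearest neighbors, acceptance band of
±2.5 standard deviations), thinned with a 5 mm point-to-point greedy
subsampling (deterministic, input order, spatial hash), and normalized
against a session digital terrain model (DTM).

The DTM is a rasterize-then-fill estimate: 10 cm cells, per-cell ground
elevation = 5th percentile of the in-cell heights (robust to low
outliers), gap cells filled by inverse-distance interpolation from the
nearest valid cells, bilinear interpolation between cell centers, and
nearest-cell extrapolation at the border. The 5th percentile rides up
into the canopy wherever occlusion removes all true ground returns — an
intrinsic failure mode of ground estimation from above-canopy scans. We
keep it deliberately: the simulator's occlusion control reproduces it,
and the test suite asserts that DTM error grows monotonically with
occlusion strength.

The band of the SOR filter is closed with a relative numerical tolerance
(1e-9) so that configurations in which every point has an identical
neighborhood statistic are kept in full regardless of floating-point
rounding.

## Two-phase registration

**Phase 1 — terrain ICP.** The two sessions' DTM cell centers are aligned
with point-to-point ICP (nearest-neighbor correspondences, rejection
beyond 0.5 m, SVD update, tolerance 1e-6 m, at most 100 iterations). ICP
needs a coarse initial pose; in the field this comes from the scanner's
GPS and inclinometer, and the simulator mirrors it with
`coarse_pose_guesses()` — the true inverse perturbation contaminated by a
bounded error (0.3 m per axis, 1° per angle). Terrain is nearly flat, so
phase 1 fixes elevation, roll and pitch well but leaves a horizontal
slide of tens of centimeters.

**Phase 2 — bird's-eye-view (BEV) Procrustes refinement.** Both clouds
are height-normalized against the *reference* terrain and reduced to plot
centroids: vegetation mask (z > 5 cm), occupancy raster, connected
components, per-cluster re-threshold at half the cluster's maximum height
(keeping the upper canopy), components again, then a PCA filter that
keeps only clusters elongated along the row axis (first principal axis
within 30°, along-row/across-row extent ratio ≥ 1) with a plausible area.
Mutual-nearest-neighbor matching (gate 0.9 m, half the row spacing)
pairs the surviving centroids, and a closed-form planar Procrustes
superimposition — translation from the centers of gravity, rotation angle
from the sums of cross and dot products — gives the refining transform,
which is lifted to SE(3) with rotation about +Z and zero vertical change.
Finally all registered sessions are renormalized against the reference
DTM, so one ground level (Z = 0) serves the whole series.

Numerical choices in the BEV stage that the data forced:

* *Raster resolution and closing.* The occupancy raster uses 5 cm pixels
  and a 3×3 morphological closing before labeling. At survey-grade
  density (≈5 mm spacing) a finer raster would work equally well; at the
  simulator's volumetric densities a fine raster fragments a plot into
  specks. The closing bridges single-pixel gaps only.
* *Nominal cluster area.* The area filter is relative to the
  pixel-weighted median component area of the session (the area of the
  component a typical canopy pixel belongs to). A fixed nominal plot
  footprint would reject every cluster early in the season, when true
  canopy footprints are below a quarter of the plot rectangle; the
  weighted median tracks the crop's current size and is robust to many
  small fragments. An absolute nominal area can still be supplied.
* *Fragment rejection and robust refit.* Clusters much shorter along the
  row than the session's typical cluster are dropped (60% of the
  pixel-weighted median extent), because partial canopies sit off-center.
  After a first Procrustes solve the matching is repeated with a
  tightened gate (0.35 m) and pairs with residuals above twice the median
  are trimmed before re-solving (two rounds). Both guards exist because a
  handful of displaced centroids otherwise biases the rotation, whose
  error is amplified by the field's ~50 m lever arm.
* *Tie-breaking.* Equidistant nearest neighbors resolve to the lowest
  index; the whole pipeline is deterministic.

If the BEV stage finds no usable clusters (bare field, or full canopy
closure merging rows), registration falls back to the phase-1 transform,
flagged `coarse_only`.

## Evaluating registration

Quality is reported as nearest-neighbor residual statistics between a
registered cloud and its reference placement: RMS and standard deviation
of the residual norms, the directed Hausdorff distance
`d_H(A, B) = max_{a∈A} min_{b∈B} ||a − b||`, and per-axis maxima/minima
of the signed residual components. The directed form is the default;
the symmetric variant (max of both directions) is available. On the
synthetic series the comparison is exact: the same point set is placed
once by the estimated transform and once by the true one.

## Traits

Plots are cut out of each registered, renormalized cloud with a polygon
grid built once by replicating the first plot's rectangle at the layout
pitch (GeoJSON on disk; half-open containment so boundary points belong
to exactly one plot). Per plot and session: CH as the maximum or the
95th/99th percentile (type-7 linear interpolation, the numpy/R default)
of all normalized heights in the plot; CA by projecting vegetation points
(z > 5 cm) to a binary mask and counting occupied pixels; CV = CA·CH.
Empty plots yield missing values, never zeros.

The CA mask pixel deserves care. With survey-grade point spacing a fixed
1 cm pixel is the natural choice. At lower densities a fixed fine pixel
undercounts badly (most pixels inside the canopy hold no point), so by
default the pixel is chosen per plot as ~2.2 divided by the square root
of the projected point density, floored at 1 cm and capped at 8 cm, and
single-pixel holes are closed before counting. On simulated canopies
this keeps the estimate within a few percent of the analytic footprint
ellipse from about 40 days after planting; at seedling scale the
footprint itself approaches the raster resolution and per-plot errors up
to roughly the pixel fraction of the perimeter remain.

Light interception is summarized by the intercepted fraction
`IPARf = (PAR_above − PAR_below)/PAR_above` and its saturation with
canopy volume, fitted by nonlinear least squares as the Beer–Lambert
form `IPARf = a (1 − exp(−b·CV))` with `a ∈ (0, 1]`. The input check
tolerates IPARf slightly outside [0, 1] (sensor noise); the fit starts
strictly inside the parameter box, since a start pinned on a bound can
stall a projected Levenberg–Marquardt step. Goodness of fit uses the
standard error of regression `SER = sqrt(SS_res / (n − (p + 1)))` with
p = 2 coefficients, alongside R², RMSE and MAPE for CH validation.

## Growth modeling

Trait trajectories follow sigmoid growth. Three families are supported,
all parameterized by asymptote `A`, rate `k` (1/day) and inflection-time
parameter `Ti` (days after planting):

* logistic `W = A / (1 + e^{−k(t−Ti)})` — symmetric, `W(Ti) = A/2`;
* Gompertz `W = A e^{−e^{−k(t−Ti)}}` — right-skewed, `W(Ti) = A/e`;
* Richards-3P `W = A (1 + e^{−k(t−Ti)})^{−2}` — the Richards family with
  the shape exponent fixed at ν = 0.5, keeping three parameters.

The fitted model is hierarchical: genotype-specific `A_g` and `Ti_g`, a
single rate `k` shared by all genotypes (freeing `k` per genotype
routinely breaks convergence on one-season data), a replicate (block)
random intercept on the asymptote `u_r ~ N(0, σ_u²)`, and residual noise
`N(0, σ²)`. Because the model is linear in the asymptote given the curve
shape, maximum likelihood splits into two layers: for any candidate
`(k, Ti_1..G, σ_u²/σ²)` the asymptotes are profiled out by generalized
least squares (both design matrices have one nonzero entry per row, so
the algebra reduces to grouped sums and a G×G solve) and σ² has a closed
form; L-BFGS-B with jittered restarts searches the remaining parameters.
Initialization is data-driven: `A₀ = 1.05·max`, `Ti₀` at the half-max
crossing of the per-genotype mean trajectory, `k₀ = 4·max-slope/A₀`. The
variance ratio is optimized on a log scale bounded below; hitting the
bound pins σ_u at zero and flags the fit as singular. Standard errors
come from the observed information over the fixed effects, with variance
components held at their estimates (the usual conditional
approximation). Estimation is plain ML so AIC and BIC are comparable
across families; `compare_models()` ranks fits, reports ΔAIC/ΔBIC and
computes likelihood-ratio p-values only for nested pairs — the three
fixed-shape families all have 2G + 3 parameters and are flagged
non-nested.

Genotype differences in `A` or `Ti` are tested with all pairwise Wald
z-tests, Bonferroni-adjusted by default (a Tukey studentized-range
adjustment is available; when both appear in the literature for the same
analysis we default to the stricter Bonferroni and let the user switch),
and summarized with a compact letter display built by insert-and-absorb.

## The synthetic field

The simulator emulates a single-row cotton breeding trial: by default 8
rows × 11 plots (3.05 m plots, 1.83 m row spacing, 1.52 m alleys — a
field of roughly 50 m × 15 m), a randomized complete block assignment of
an 11-genotype panel with logistic growth parameters spanning asymptotic
heights of 1.24–2.06 m (`k` = 0.06/day, inflection 49–59 DAP) and
asymptotic volumes of 2.76–7.25 m³ (`k` = 0.106/day), nine survey
sessions at 35–98 days after planting, smooth low-frequency terrain
relief (±0.2 m), 5 mm Gaussian terrain noise, 0.2% uniform outliers, and
per-session rigid perturbations up to 0.5 m per axis and 5° per angle
(the first session defines the global frame, as the first survey does in
practice). A replicate effect on the asymptote (sd 0.03 m) makes the
block random effect of the growth model real.

Plants are not modeled individually: each plot's canopy is a uniform
point sample of a half-ellipsoid whose height follows the plot's logistic
curve and whose footprint follows a second logistic tied to the volume
target, so that CA·CH reproduces the CV curve until the footprint
saturates at the plot rectangle; one apex point marks the plant terminal
so the true maximum height is attained exactly. Terrain returns under a
canopy are deleted with probability proportional to the overlying canopy
thickness, scaled by an occlusion-strength control that reaches complete
removal at 1 — reproducing the late-season DTM degradation. All
randomness flows through one seed; identical seeds give point-for-point
identical clouds.

What the simulator does *not* emulate: scanner beam geometry and
viewpoint shadows, leaf-level surface structure (point density is
volumetric, several-fold below a real multi-scan survey's surface
density), row-neighbor canopy merging, lodging, and weeds. Passing tests
therefore demonstrate the pipeline's correctness and its qualitative
failure modes, not survey-grade absolute accuracies.

## Problem sizes and determinism

Validation runs use a field-realistic geometry with reduced sampling
resolution, chosen to keep a full season's processing in the minutes
range on one core: canopy density 1,500 points/m³ and 12 cm ground
spacing for the nine-session registration study (≈0.1–0.25 M points per
session), 5,000 points/m³ on a two-row field for canopy-area validation,
and the full 11 genotypes × 8 replicates × 9 sessions table (792
records) for growth-model recovery. The demonstration pipeline
(`demo_pipeline()`, `tls4d demo`) runs a 4 × 6 field over five sessions
and writes byte-identical artifacts for a fixed seed.

## Known limitations

* The BEV refinement corrects horizontal translation and yaw only;
  vertical accuracy is owned by the terrain phase and inherits the DTM
  bias under dense canopy (about 2 cm on the synthetic series, worse at
  the final session — the same pattern the field method shows).
* Percentile canopy heights are computed over all plot points, including
  ground returns; with sparse canopies CH95 can sit well below the true
  plant height. CHmax with prior SOR denoising is the recommended
  estimator.
* The Richards family is restricted to a fixed shape (ν = 0.5); a free
  shape parameter is deliberately out of scope, as it rarely converges on
  single-season field data.
* Plot polygons are rectangles sharing one bearing; irregular plot
  shapes are not supported.
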