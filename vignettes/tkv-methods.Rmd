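---
title: "Measuring total kidney volume with a hybrid level set: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring total kidney volume with a hybrid level set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In autosomal dominant polycystic kidney disease (ADPKD), total kidney volume
(TKV) measured from T2-weighted abdominal MRI is the accepted prognostic
imaging biomarker: it grows years before renal function declines, and
height-adjusted TKV (HtTKV) together with age drives the Mayo imaging
classification (1A–1E) used to select patients for treatment. Fully manual
contouring of both kidneys takes tens of minutes per patient; estimating
equations (ellipsoid, mid-slice) are fast but imprecise on cystic kidneys.
`tkvtools` implements a semi-automated middle road: the user supplies one
seed contour per kidney on the mid-coronal slice (plus two landmark points on
a sagittal slice and a crop rectangle), and a hybrid level-set active contour
does the rest, slice by slice.

## Pipeline

1. **Load** a DICOM series (one coronal slice per file) or a NIfTI volume.
   Volumes are permuted at read time to a canonical
   (sagittal, coronal, axial) axis order using the orientation metadata, and
   all downstream code addresses axes anatomically. Missing spacing metadata
   is an error, never a silent default; a nonzero slice gap triggers a
   warning and the spacing between slices is used for volumetry.
2. **Slice selection.** Two user points on the (approximate) mid-sagittal
   slice mark the kidney's anterior and posterior extent; their span,
   dilated by a margin (default 2 slices), selects the coronal working range.
3. **Pre-processing**, in fixed order:
   *motion* — each slice is rigidly registered (rotation + in-plane
   translation) to its already-corrected neighbour, chaining outward from a
   central reference slice;
   *bias field* — a smooth multiplicative field `exp(poly2(x, z))` per slice
   is estimated by minimising the entropy of the corrected intensity
   histogram (64 bins, linear binning), with the field normalised to unit
   mean so slice brightness is preserved;
   *inter-slice gain* — per slice, "bright tissue" is everything above half
   the slice's robust maximum (99th percentile, to resist hot pixels); each
   slice is scaled so its mean bright-tissue intensity matches the median of
   those means across slices. The threshold is deliberately relative to each
   slice's own maximum: that is what makes the construct invariant to the
   gain drift it corrects. A volume-level floor only vetoes slices containing
   no tissue at all, which keep multiplier 1 with a warning.
4. **Crop** a user-checked rectangle over the slice range. The crop offset is
   recorded so masks map back to the full grid exactly.
5. **Segment.** Intensities are first rescaled so the volume's 99th
   percentile maps to 255, making the region threshold meaningful across
   scanners. The seed polygon initialises a signed-distance field (negative
   inside) on the mid-coronal slice, which evolves under the hybrid energy
   (below). The final mid-slice region then propagates in both directions:
   each next slice is initialised from the previous slice's final region,
   eroded by one voxel (so the contour cannot leak where the kidney narrows)
   and intersected with the one-voxel-dilated super-threshold set
   `{I > mu}`; propagation in a direction stops when that initialisation is
   empty or when the evolved region's mean intensity falls below `mu`
   (by the energy's own region model such a region is background, and at the
   published force weights a large stranded contour on background cannot
   shrink to empty within the iteration budget).
6. **Volumetry.** Volume is the sum over slices of region area times slice
   thickness, reported in ml; TKV is right + left, kept separate in the
   report so side-specific errors stay visible; HtTKV divides by height in
   metres.

## The hybrid level-set energy

With `phi` the level-set field (negative inside), `H` a smoothed step and
`g` the edge map,

$$E(\phi) = -\alpha \int_\Omega (I-\mu)\,(1 - H(\phi))\, d\Omega
           + \beta \int_\Omega g\,|\nabla H(\phi)|\, d\Omega .$$

The first (region) term rewards enclosing voxels brighter than `mu` and
expelling darker ones; the second is a geodesic edge term: contour length
weighted by `g = 1/(1 + c\,|\nabla I|^2)`, which is 1 on flat image regions
and drops toward 0 on boundaries, so shortening the weighted length pulls
and pins the contour onto edges. Gradient descent gives

$$\phi_t = \delta_\varepsilon(\phi)\,\big[\beta\,\mathrm{div}\!\big(g\,
\nabla\phi/|\nabla\phi|\big) - \alpha\,(I-\mu)\big],$$

i.e. edge-weighted curvature flow plus edge attraction
(`∇g · n`), biased by the region force. The denominator form of `g` with a
plus sign is used; a minus sign would be singular or negative at strong
edges.

### Parameters

| symbol | meaning | default | notes |
|---|---|---|---|
| `alpha` | region weight | 0.01 | operating point of the published tool |
| `beta` | edge weight | 100 | idem |
| `mu` | region threshold | 50 | on the working 0–255 scale (99th pct → 255) |
| `iterations` | evolution steps | 100 | stopping rule; near-converged (see tests) |
| `cc` | edge-map slope | 1 | calibrated on the phantom suite |
| `heaviside_eps` | step smoothing | 1.5 voxels | `delta` band of the update |
| `smooth_sigma` | pre-gradient blur | 2 voxels | sets the edge capture range |
| `dt` | base time step | 0.5 | see numerics below |

The contract for seeds mirrors the tool's intended use: the polygon is drawn
*near* the kidney boundary. The edge-attraction capture range (a few voxels,
set by `smooth_sigma`) and the weak region force then finish the job; the
tests show the final mask is insensitive (Dice ≥ 0.99) to seed boundaries
within ±3 voxels of truth.

### Numerics

At `alpha/beta = 10^{-4}` the stable explicit step for the curvature
(diffusion-like) part of the flow is so small that the region and
edge-attraction forces would move the interface by well under a voxel in 100
iterations. The update therefore uses a *pointwise preconditioned* step
`dt_g = dt/(1 + 4\,dt\,\beta g)`: wherever `g` is large (flat regions, where
the diffusion bound binds) the step shrinks to keep the effective diffusion
number ≤ 1/4, and wherever `g` is small (near edges) the advection and
region forces act at full pace. A positive pointwise step rescaling does not
move the stationary contours of the energy. Updates are additionally clamped
to half a voxel per iteration, the smoothed delta uses a unit-peak profile
`eps^2/(eps^2 + phi^2)`, and `phi` is rebuilt as an exact signed distance
(Euclidean distance transform) every 10 iterations. Evolution is fully
deterministic.

## Comparison estimators and classification

The ellipsoid estimate is `pi/6 · L · W · D` from caliper measurements and
refuses atypical (Mayo class 2) morphology, for which it is unreliable. The
mid-slice estimate is `coefficient · mid-slice area · n_slices · thickness`
with the published single-mid-slice coefficient 0.624 as default. Both are
homogeneous of degree 3; on a slab the mid-slice form is exact at
coefficient 1.

Mayo class 1 subtypes derive from the implied annual growth rate
`r = (HtTKV/150)^{1/age} − 1` (theoretical 150 ml/m at age 0), with
thresholds 1.5 / 3 / 4.5 / 6 %/yr. Rates within 0.1 percentage points of a
threshold (default) are flagged *borderline* for manual reanalysis; the
default tolerance is chosen so that the two classic borderline presentations
(age 51 with HtTKV 678 ml/m at 1B/1C; age 36 with 256 ml/m at 1A/1B) are
flagged.

## Agreement statistics

Bland–Altman bias, SD and limits of agreement (bias ± 1.96 SD) are computed
on raw or percentage differences; the percentage denominator defaults to the
reference method (so negative means the test method underestimates), with
the classical pair-mean denominator available. Test–retest CoV is the root
mean square across subjects of per-subject (SD of repeats / mean). The
sample-size planner asks for the smallest `n` such that both expected limits
of agreement, padded by `(t_{1-\alpha/2,\,n-1} + z_{power})` times the
limit's approximate sampling SD `\sigma\sqrt{3/n}`, stay inside the
clinically acceptable band `±\delta`; the design is infeasible when
`|bias| + 1.96\sigma \ge \delta`. At bias 2%, SD 5%, `\delta` 15%,
`\alpha` 0.05 and power 0.80 the planner returns 60 pairs — the suite's
anchor — and `n` is monotone in the SD and in the bound.

## The phantom generator

Validation runs on synthetic volumes with exact ground truth, emulating the
acquisition the pipeline targets (coronal stacks, 1.5 mm in-plane and 4 mm
slices by default, zero gap):

- two ellipsoidal kidneys with anatomical proportions
  (length : width : depth ≈ 2.1 : 1.25 : 1), tilted in the coronal plane,
  scaled analytically to a requested TKV (`4/3·π·abc` per kidney);
- hyperintense spherical cysts placed fully inside the parenchyma;
- an abdominal cross-section: muscle-dark interior, bright subcutaneous fat
  ring, air outside — besides realism, the body outline shared by adjacent
  coronal slices is what anchors inter-slice registration, as in real scans;
- smooth 3D anatomical texture (superposed random cosine waves, 18–40 mm
  wavelengths): 5% amplitude in parenchyma, 35% in the background clutter.
  A piecewise-constant phantom makes inter-slice registration ill-posed
  (a smaller cross-section nested in a larger one gives a flat or
  tangency-biased objective), which no real image exhibits;
- degradations in fixed order gain → bias → motion → noise: per-slice global
  gain drift, a smooth multiplicative quadratic bias field per slice,
  small per-slice rigid motion (the central slice is the identity), and
  additive Gaussian noise. Every injected degradation is returned so each
  correction stage is scored against exact truth.

All randomness derives from one integer seed; generation is bit-for-bit
reproducible. The `phantom_cohort()` helper builds a deterministic cohort
whose analytic TKVs are log-evenly spaced across a requested range — the
validation suite uses 30 cases spanning 258–3680 ml, the spread of a
real-world development cohort, with cysts, noise and gain drift.

**Oracle isolation.** Each pre-processing oracle exercises its own
degradation on a phantom that isolates the mechanism: the gain oracle runs
body-free (with a body, per-slice bright-tissue *composition* varies between
slices, so multipliers are deliberately not proportional to 1/gain — a
property of the normalisation construct itself), and the bias oracle runs
with texture-free parenchyma (texture is irreducible within-tissue variance
that no bias correction can, or should, remove). The segmentation cohort
carries cysts, noise and gain drift; motion and bias are validated by their
dedicated oracles rather than re-run on all 30 cases, keeping the cohort a
test of segmentation and normalisation at tractable cost.

**What the phantom does not emulate** — and therefore what passing tests do
not establish about clinical data: organ shapes beyond (tilted) ellipsoids
and spheres, partial-volume ramps at tissue interfaces, Rician noise
statistics, vendor-specific intensity scales, exophytic cysts deforming the
outline, hilum and vessel anatomy (conventionally excluded from manual
tracing but not removed by this tool), and neighbouring organs touching the
kidney — the bright-liver hard case is available (`liver_abut = TRUE`) as a
stressor but is not part of the accuracy cohort. Known failure modes of the
approach on real data — undersegmentation at exophytic cysts,
oversegmentation at large vessels — have no mitigation here.

## Degenerate inputs and edge cases

Constant slices pass through bias correction unchanged; blank or
near-structureless slices keep identity motion transforms (with a warning)
and multiplier 1 in gain normalisation; empty masks have volume 0 and two
empty masks have Dice 1 by convention; a seed polygon must be simple with
positive area and inside the slice; a mid-slice segmentation that comes back
empty is an error, not an empty report.

## Problem sizes

The shipped test suite renders phantoms at 1.5 mm in-plane / 4 mm slices
with TKVs from 258 to 3680 ml (grids up to roughly 310 × 42 × 250 voxels for
the largest cases), a 30-case accuracy cohort, and smaller dedicated
phantoms for the correction oracles; these sizes were chosen as the smallest
that still span the clinically relevant size range at the target resolution.

## Known limitations

- 2D per-slice evolution with inter-slice propagation, not a volumetric 3D
  level set; strongly oblique kidneys could defeat the slice chaining.
- Single-frame DICOM, explicit-VR little-endian only (the profile this
  package writes); enhanced multi-frame DICOM is out of scope.
- No automatic hilum or vessel exclusion; volumes follow the outer contour.
- The ellipsoid and mid-slice estimators consume externally measured inputs;
  no automated caliper measurement from masks is exposed beyond the internal
  helpers used for phantom comparisons.
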