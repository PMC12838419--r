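---
title: "Fusing intravascular OCT with CCTA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing intravascular OCT with CCTA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corofuse)
```

This vignette explains the science and the numerical machinery behind
`corofuse`: what each pipeline stage models, which tunable parameters
matter and why their defaults are what they are, what the synthetic phantom
generator does and does not emulate, and where the genuinely open design
choices were settled.

## The fusion problem

Intravascular OCT images the lumen of a coronary artery at roughly 15 µm
resolution during a motorized catheter pullback (here 40 mm/s over a 75 mm
travel), but each frame is a 2D section with no absolute 3D pose, and the
catheter twists unpredictably as it is withdrawn. CCTA provides the missing
3D context — vessel centerline, side branches, calcifications — but at
about 0.4 mm resolution, roughly 400× coarser than OCT in-plane. The
pipeline lets CCTA supply geometry and OCT supply lumen detail: contours
extracted from the pullback are de-twisted, anchored to the CCTA centerline
at a bifurcation carina visible in both modalities, merged with the CCTA
surface point cloud, and re-meshed into a single watertight model.

## Contour extraction from annotated frames

The OCT console exports frames with the lumen border pre-annotated in a
distinct colour. Extraction is a four-step chain
(`extract_annotation_mask()` → `hull_and_spline()` → `pixels_to_mm()`
wrapped by `process_pullback()` / `process_pullback_path()`):

* **Colour threshold** — pixels within `color_tol` (default 30/255 per
  channel) of the annotation colour (default pure green). The tolerance is
  generous because compressed exports bleed colour.
* **Gaussian smoothing + re-threshold** — `sigma = 2` px kills isolated
  same-colour speckles and bridges dashed annotation gaps up to about
  2·sigma; the smoothed intensity is cut at `threshold = 0.5`. A thin
  (1 px) annotation would fall below the absolute cut, so the mask falls
  back to a max-relative cut in that case — the export line width is not
  assumed.
* **Convex hull + periodic spline** — the smallest convex polygon around
  the mask foreground, densified by arc length and interpolated by a
  periodic cubic spline sampled at `n_samples = 256` points. Densification
  matters: a cubic spline through sparse hull corners overshoots on long
  edges. Because the hull rides the *outer* pixel edge of the annotation
  band, the contour is pulled inward by half the estimated band thickness
  (mask area / hull perimeter) plus half a pixel; this self-calibrating
  compensation removes a ~1.5 px radial bias and is skipped for filled
  masks.
* **Calibration** — 103 px = 1 mm, origin at the image centre (the
  catheter axis), y flipped to a right-handed frame. Any constant offset
  this convention introduces is absorbed by the registration translation.

The physical distance between frames is deliberately *not* hardcoded: the
pullback speed is known (40 mm/s) but the frame rate of the recording is
not, so `oct_calibration()` takes either `frame_spacing_mm` directly
(default 0.2 mm) or a `frame_rate` from which spacing is derived.

## Twist correction

Catheter twist is estimated per consecutive contour pair: the later contour
is rotated about the catheter axis over a ±3° window in 0.1° steps and the
rotation maximising the intersection area (exact polygon clipping on
256-point resamplings, not rasterisation) is kept; corrections accumulate
along the pullback (`correct_twist()`). Ties break toward the smallest
magnitude, then negative, so rotationally symmetric lumens report zero. A
true inter-frame twist beyond the window clamps at ±3° and is logged, not
silently widened.

One behaviour worth knowing: when consecutive sections are *nested* —
one strictly inside the other, as happens along a smooth stenosis shoulder
with near-circular lumens — the overlap objective is flat in the rotation
angle and extraction noise decides the argmax. On analytic elliptical
pullbacks with axis ratio ≥ 1.2 the estimator recovers smooth injected
profiles to ~0.03°/frame; on rendered noisy frames individual increments
can wander, which leaves area-based downstream metrics untouched (the
rotation is about the catheter axis, so sections barely move) but is the
reason the twist-recovery guarantee is stated for elliptical lumens.

## Registration

The centerline is resampled so point spacing equals the frame spacing, and
carries rotation-minimizing (double-reflection) transport frames. Frenet
frames were rejected: they are undefined on straight segments and inject
spurious twist exactly where the stack must stay rigid. The landmark is the
bifurcation carina: its image-side position is picked on one frame, its
CCTA-side position is the midpoint of the projection points on the main and
side branch, snapped to the nearest centerline point (landmarks whose
midpoint is > 5 mm from the centerline are rejected). The in-plane rotation
aligns the frame's carina direction — measured from the lumen centroid, so
an off-centre catheter does not bias it — with the side-branch direction
projected into the section plane. All other frames inherit the same
in-plane transform at consecutive centerline points on both sides of the
landmark: interlocking preserves relative frame poses, and out-of-plane
rotation is deliberately not modelled (the catheter path is assumed to
follow the centerline). An optional `centroid_snap` mode instead centres
every contour on its centerline point; the default keeps the rigid offset.

## Fusion and reconstruction

CCTA lumen meshes are sampled into labeled point clouds (vertices plus
area-weighted face samples, default 10 points/mm²). CCTA points whose
nearest OCT contour point lies strictly closer than 0.35 mm are removed by
a k-d tree radius query; equality keeps the point. Residual cleanup —
interactive in a GUI workflow — is replaced by declarative region
predicates (spheres, boxes, centerline tubes) recorded in the
configuration, which keeps runs reproducible.

Surface reconstruction is implicit: a smooth signed distance is blended
from the oriented points (locally weighted plane distances, k = 10
neighbours), and its zero set is extracted by marching tetrahedra on a
voxel grid (default 0.15 mm) restricted to a band around the cloud, then
cleaned (largest component, fan hole-filling, outward orientation). Any
method meeting the same watertightness/accuracy contract would be
conformant; this one is deterministic, needs no external binaries, and on
synthetic tubes reproduces station radii to ~1%. Two numerical details are
deliberate: the grid is shifted by an irrational fraction of a voxel so
flat axis-aligned features never coincide with grid planes (grazing zero
sets produce sliver triangles), and below ~0.5 mm voxels the residual
station-radius error (~1%) is the bias of the implicit blend, not the
grid — refining further does not help.

The wall is a uniform 1 mm outward offset of the lumen (per-vertex
area-weighted normals by default; an implicit re-extraction mode resolves
self-intersection at sharp stenoses). The solid is represented as two
nested shells (outer surface plus inward-facing lumen surface), so the
enclosed material volume is their signed-volume difference.

## Calcifications and blooming

CT blooming makes calcifications look systematically larger than they are;
comparisons of paired OCT/CCTA cross-sections (equal-area "theoretical"
radius, area, perimeter) show CCTA radii exceeding OCT by a few tenths of
a millimetre, motivating a uniform 0.5 mm inward correction. In section
planes the correction is a polygon erosion with round joins (erosion of a
smooth anatomic contour should not mint corners; mitred joins are
available). In 3D the equivalent inward implicit offset is provided; the
section-plane erosion is the validated reference, and whether the original
workflow applied the correction per-section or isotropically in 3D is left
open — both modes exist. Embedding unions the corrected calcification
solids with the wall; when the lumen mesh is available the wall's distance
field is computed as `max(−d_lumen, d_lumen − t)`, which is markedly more
robust (and ~10× faster) than querying a dense two-shell reconstruction
whose sliver faces make pseudonormal signs fragile.

## Validation metrics

* **Vertex distance (VD)** — for each vertex of the derivative model, the
  distance to the nearest *surface point* of the original model
  (point-to-triangle, not nearest-vertex, to avoid tessellation-density
  artifacts; a symmetric option exists). Distances strictly below 0.05 mm
  are excluded from the median/IQR — a conservative choice, since dropping
  near-zero values can only raise the median; if everything is excluded
  the comparison is flagged degenerate rather than reported as zero.
* **Area profiles** — the model is sectioned perpendicular to the
  centerline at every station; the component nearest the centerline point
  is the lumen (guarding against side-branch cuts); missing sections are
  `NA`, never zero. Profiles are z-scored, `z = (A − µ)/σ` with the
  population σ (divide by N; switchable), which removes systematic size
  offsets from printing or imaging scale. Paired comparisons report the
  absolute area difference (median, IQR with the linear-interpolation
  quartile convention) and the mean/sd of |z₁ − z₂|; z-scores are
  re-normalised over the shared stations so both profiles are compared on
  the same support.
* **Stenosis** — `%AS = (RVA − MLA)/RVA × 100`. The MLA is the profile
  minimum (ties resolve distally so a proximal reference exists); the RVA
  automates the "healthier proximal segment" as the maximum of a width-5
  moving median proximal to the MLA — a manual clinical choice cannot be
  replicated exactly, so the automation is documented rather than hidden.
* **Side-branch spacing** — along-pullback distance between two frames,
  `|i − j| ×` frame spacing, reported to the millimetre.

## The synthetic phantom generator

`phantom_spec()` defines a parametric vessel: centerline shape (straight,
planar arc, helix, or spline through waypoints), length (default 75 mm, a
typical pullback travel), base lumen radius, Gaussian stenoses
`r(s) = r₀(1 − Σ dᵢ exp(−(s−pᵢ)²/2wᵢ²))` (chosen for differentiability and
an analytic severity `%AS = (1 − (r_throat/r₀)²)·100`), area-preserving
ellipticity (default 1.25 — twist estimation needs a non-circular lumen to
grip on), side branches, wall calcification slabs with a blooming offset,
a smooth seeded per-frame twist profile (default bound 0.5°/frame), and
radial contour noise (default 0.01 mm, annotation jitter at the OCT axial
resolution scale). Everything is deterministic under the spec's seed.

Pseudo-OCT frames are the analytic section, twisted and offset, drawn as a
3 px border in the annotation colour over multiplicative speckle with a
bright catheter ring — enough to stress colour thresholding without
modelling OCT light transport. The CCTA-like cloud quantises surface
samples to the scanner resolution (default 0.4 mm) and adds radial noise of
half that; calcifications are dilated by their blooming offset. Two presets
ship as scenario archetypes: `"patient12-like"` (89 %AS, no calcification)
and `"patient7-like"` (80 %AS, calcified), each with two side branches
16 mm apart.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate on real data: cardiac-motion deformation between frames,
blood/artifact pixels inside the lumen, eccentric non-elliptical lumen
shapes, catheter paths departing from the centerline, CT beam-hardening
beyond a uniform dilation, and segmentation errors in the upstream
console/workstation software whose exports the pipeline consumes.

## Problem sizes and end-to-end behaviour

The shipped end-to-end runs image the feature-bearing 22–26 mm of each
preset at 0.4 mm frame spacing (the recording frame rate is a free
parameter; the default calibration keeps 0.2 mm) and reconstruct at
0.15 mm voxels, with the whole-model calcification union at 0.25 mm. Under
those conditions the full loop — render, extract, de-twist, register,
fuse, reconstruct, section — recovers the analytic stenosis severity
within about one percentage point and branch separations exactly, which
the test suite asserts at the looser ±3 points / ±1 mm bounds.

## Known limitations

* The twist estimator degrades on nested near-circular sections (above);
  its guarantee is for lumens with axis ratio ≥ 1.2.
* Hole filling is centroid-fan based and intended for small reconstruction
  and end-cap holes, not arbitrary topology repair.
* Branch junctions in the phantom lumen mesh are unstitched tube unions;
  the implicit reconstruction blends them smoothly, but the input mesh
  itself is only used as a sampling source and analytic truth.
* The wall solid seals the vessel ends (two nested shells); models
  intended for flow experiments need the ends opened downstream.
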