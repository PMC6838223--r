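---
title: "Image-based strain analysis of post-EVAR aneurysms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based strain analysis of post-EVAR aneurysms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After endovascular repair (EVAR) of an abdominal aortic aneurysm (AAA), the
excluded aneurysm sac should shrink. When it does not — because of
endoleaks, endotension, or graft failure — the sac re-pressurizes and the
rupture risk returns. Surveillance today compares the maximum sac diameter
between follow-up CT-angiography (CTA) scans, a one-number summary that
misses most of what the images contain. `evarstrain` extracts a richer
signal: the full 3D deformation of the thrombus between two follow-up
scans, converted into voxel-wise biomechanical strains and summarized into
per-patient features that correlate with long-term prognosis.

## The pipeline

Given two scans `t1` (reference) and `t2` of the same patient, plus a
thrombus segmentation and the lowest-renal-artery landmark for each scan:

1. **Bone segmentation** (`segment_bones`): thresholding at 1100 HU plus
   26-connected component filtering (components below 500 voxels dropped).
   Bones are the only genuinely rigid structures in the abdomen.
2. **Rigid alignment** (`register_rigid`): a 6-DOF transform minimizing the
   mean squared intensity difference over the (2-voxel-dilated) bone mask,
   initialized by the renal-landmark translation and optimized by
   regular-step gradient descent with a 2-level schedule. Both images are
   Gaussian-smoothed per level before the metric is evaluated, and samples
   that fall outside the moving volume are excluded from the mean — without
   both measures the optimum is visibly biased by edge aliasing and
   field-of-view clipping.
3. **Centerline extraction** (`segment_lumen`, `skeletonize`,
   `prune_to_main_branches`, `merge_bifurcation`): adaptive region growing
   of the contrasted lumen (interval `mu +/- 2.5 sd`, re-estimated per
   flood-fill sweep), hole filling, distance-ordered homotopic thinning,
   geodesic extraction of the three main branches (aortic trunk and the two
   endograft limbs), and merging of the limbs into a single path by taking
   limb midpoints at matched arc-length fractions. Lumen segmentation runs
   in each scan's native lattice; the second scan's path is then carried
   through the rigid transform (interpolated resampling suppresses image
   noise enough to stall the adaptive interval otherwise).
4. **Straightened CPR** (`straighten`): each volume is resampled on planes
   orthogonal to its centerline (sampled every 1 mm, smoothed at a 5 mm
   scale first), with in-plane frames built from a fixed sagittal
   projection direction. The straightened volumes are aligned by the
   integer index offset of the straightened renal landmark
   (`align_straightened`).
5. **Deformable registration** (`level_set_register`): the straightened
   thrombus volumes evolve for exactly 200 level-set-motion iterations;
   the velocity is `residual * grad(w) / (|grad w|^2 + eps)` (residual =
   fixed minus warped image), a per-voxel step cap of 0.5 voxels, and Gaussian
   smoothing (sigma 1 voxel) of the accumulated field. The inputs are the
   straightened thrombus segmentations as lightly smoothed indicator
   images: the segmentations are what both scans share; their level sets
   are exactly the surfaces whose motion the method needs. Registration
   quality is reported as the Dice overlap of the warped moving mask
   against the fixed mask (masks are transported anti-aliased: the
   indicator is interpolated linearly and thresholded at half).
6. **Strain analysis** (`displacement_gradient` ... `strain_summary`): the
   recovered displacement field U (mm, on the fixed straightened lattice)
   yields the deformation gradient `F = grad(U) + I` by central
   differences, the right Cauchy-Green tensor `C = F'F`, and per-voxel
   principal stretches `sqrt(lambda_i)`. Where the largest stretch exceeds
   1 its eigenvector is the tensile strain unit vector (magnitude
   `sqrt(lambda_1) - 1`); where the smallest is below 1 its eigenvector is
   the compressive one. Voxels failing either strict inequality are
   triaxially compressed or tensed and contribute no vector.
7. **Prognosis features** (`orientation_pca`, `build_features`,
   `evaluate_cv`): the orientation (second-moment) matrix
   `M = mean(v v')` of each unit-vector field is eigendecomposed; the
   three principal axes, flattened, give 9 features per field (18
   combined). A linear SVM (cost 1, per-fold z-scoring) is evaluated by
   stratified 4-fold cross-validation repeated 10 times, with ROC and
   precision-recall curves vertically averaged on 101-point grids.

The scientific intuition: a growing (unfavorable) sac bulges laterally, so
its tensile strain vectors wrap tangentially around the wall while its
compressive vectors point radially — exactly the pattern of an internally
pressurized cylinder. A healing (favorable) sac shrinks mildly and
irregularly, so its strain directions are disordered. The orientation-PCA
axes capture this global order/disorder difference.

## The phantom generator

No clinical scans ship with the package; `phantom_spec()` /
`generate_case()` emulate them. One case contains a vertebral column with
disc gaps, pedicles and two iliac blocks (1200 HU), a contrasted lumen
(400 HU, radius 6 mm) that splits into two 4.5 mm branches below 30% of
the volume height (trunk and branch segments overlap by 2 mm so the vessel
is continuous through the junction), and an ellipsoidal thrombus sheath (60 HU, semi-axes
16 x 14 x 24 mm) on a 88 x 88 x 112 lattice with 0.8 x 0.8 x 1.0 mm
voxels. The scene is evaluated analytically with ~1-voxel soft
(signed-distance) edges — point-sampling hard shapes would quantize every
boundary to the lattice phase and bias intensity-based registration, while
soft profiles reproduce the sub-voxel boundary encoding that real CT gains
from partial-volume averaging. A 0.6-voxel Gaussian PSF and 5 HU of
additive noise follow.

The second timepoint applies a rigid body motion (rotation up to 4
degrees, translation up to 8 mm by default; the recovery study uses 5
degrees / 20 mm) and a closed-form aneurysm deformation:

* **Unfavorable**: an outward radial bulge `U = a g(z) h(r) w(phi) r_hat`
  with a C^3 (septic smootherstep) axial bump `g` of 20 mm half-width, a
  radial ramp `h` rising from the lumen edge over 6 mm, and an angular
  window `w` suppressing displacement toward the spine (bones must remain
  exactly rigid, and real AAAs bulge anterolaterally for the same reason).
  Amplitudes are drawn from 3-6 mm per case, straddling the 5 mm
  diameter-change threshold used clinically. The C^3 profiles make central
  differences of the sampled field converge to the hand-derived Jacobian
  at second order, which the tests verify by grid halving.
* **Favorable**: a mild inward shrink (1.5-2.5 mm) plus ten random-phase
  smooth harmonics (radial, axial and azimuthal; ~0.35 mm each) under the
  same envelope, so that strain directions are disordered and the mean
  displacement is roughly a quarter of an unfavorable bulge.

The second scan is synthesized exactly: each t2 lattice point is pulled
back through the inverse rigid motion and the inverted deformation
(damped fixed-point iteration with relaxation 0.45 — the plain iteration
diverges where the radial displacement gradient exceeds 1) and the
analytic scene is re-evaluated there. Ground truth therefore includes
exact masks at both timepoints, the forward Lagrangian displacement field,
the rigid transform, centerlines and landmarks.

What the phantom does **not** emulate: curved aortic axes (the CPR is
instead validated on a quarter-torus fixture), stent-graft metal and
calcification, spatially correlated CT noise, breathing or bowel motion,
segmentation errors in the thrombus masks (phantom masks are exact), and
mechanically simulated (as opposed to kinematically prescribed)
deformations. Passing the cohort tests therefore demonstrates that the
pipeline recovers known smooth deformations and their strain patterns
under realistic geometry, contrast and noise — not that it handles every
clinical artifact.

## Numerical choices

* World convention: `world = origin + spacing * index`, 0-based indices,
  axis-aligned orientation; displacements in mm.
* Out-of-support samples use the volume minimum (CT air); the rigid metric
  instead *excludes* them, since a background fill rewards transforms that
  push clipped anatomy back inside.
* Strict stretch inequalities carry a 1e-12 guard so pure rotations (C = I
  to machine precision) yield no strain vectors.
* Eigenvector signs are canonicalized (largest-magnitude component
  positive); orientation PCA is computed on the uncentred second-moment
  matrix, which is invariant to the signs — the centred variant exists
  behind `center = TRUE` for comparison.
* Voxels with `det F <= 0` (folding) are counted, warned about and
  excluded from summaries.
* Degenerate growth in `segment_lumen` (iteration cap or more than half
  the volume) is flagged; `resample_centerline` is exactly idempotent at
  an unchanged sampling distance; centerline smoothing keeps endpoints
  fixed.
* The adaptive region-growing interval is seeded from the 3 x 3 x 3
  neighbourhood of the seed: a single voxel has zero variance and the
  1 HU floor would stall growth on any noisy image.

## Problem sizes and defaults

The phantom lattice (88 x 88 x 112) and the straightened lattice (0.8 mm
in-plane over an 80 mm extent, 1 mm slices) were chosen so a full case —
generation through strain features — runs in roughly half a minute, and
the study-scale analyses (a 22-case cohort, the 20-pair registration
study, the 20-transform rigid-recovery study) complete on one CPU in well
under an hour combined. The registration bounding box is the thrombus box
dilated by 10 voxels. All stage parameters are exposed through
`pipeline_params()`, `segmentation_params()` and `deformable_params()`;
the defaults above are the ones every reported number uses.

## Known limitations

* The two scans are compared on the first scan's lattice; differing
  acquisition resolutions are reconciled by resampling the moving scan,
  which loses information when the second scan is finer.
* The strain field inherits any error of the thrombus segmentations; with
  segmentation-driven registration, intensity texture inside the thrombus
  does not contribute.
* Orientation-PCA features describe global order of strain directions;
  focal deformations smaller than the sac do not dominate them.
* The straightened-frame construction uses a single fixed projection
  direction and fails (by design, with an error) if the vessel tangent
  approaches it within 5 degrees.
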