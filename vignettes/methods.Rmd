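---
title: "Statistical shape and appearance modelling of the femur and 2D-3D reconstruction from simulated radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: femur SSAM and 2D-3D reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After major trauma, orthopaedic reconstruction needs the premorbid
three-dimensional shape of a long bone, but 3D imaging (CT/MRI) is not
always available. This package implements a complete pipeline that recovers
the 3D shape of a femur -- possibly with a large distal defect -- from one
or two plain radiographs, using a statistical shape and appearance model
(SSAM), and that quantifies how good such reconstructions are in the terms
surgeons care about: surface error and anatomical angles.

Because no suitable public cohort of corresponded femur CT data exists, the
package ships a parametric femur *phantom* generator that plays the role of
the cadaver cohort: every stage of the pipeline is exercised, and every
claim in the test suite is checked against quantities the generator knows
analytically.

## The model

Each training specimen is represented by one long vector: the concatenated
coordinates of the nodes of a tetrahedral mesh with shared topology,
optionally followed by one Hounsfield-unit (HU) value per tetrahedral cell.
Given $n$ corresponded specimens $x_1, \dots, x_n$, the model is the mean
$\bar x$ and the eigenvectors $e_i$ (modes of variation) and eigenvalues
$\lambda_i$ of the sample covariance, computed through the thin SVD of the
centred data matrix (equivalent to the dual $n \times n$ formulation, since
$n \ll \dim x$). An instance with mode weights $b$ is

$$x(b) = \bar x + \sum_i b_i \sqrt{\lambda_i}\, e_i,$$

so weights are in standard-deviation units: `b = 0` is the mean, and a
plausible bone stays within roughly $|b_i| \le 3$. At most $n - 1$ modes are
retained (the rank of centred data).

**Shape/appearance weighting.** A joint PCA of millimetres and Hounsfield
units depends on their relative scale, which the underlying method
description leaves open. We rescale the appearance block so its total
standard deviation equals the shape block's, store the constant in the
model, and undo it on instantiation. With this choice neither block
dominates the covariance; the tests exercising shape recovery are
insensitive to it.

## Model building

* **Rigid alignment** (`rigid_align`): iterative closest point, with
  point-to-*triangle* correspondences and closed-form (Kabsch) updates. The
  alternation never increases the closest-point RMS.
* **Correspondence** (`correspond_ffd`): a reference surface is morphed
  onto each target with a coarse-to-fine cubic B-spline control lattice
  (default $4^3 \to 6^3 \to 10^3$), fitted by ridge least squares to
  closest-point displacements. Two details matter and are deliberate:
  forward correspondences constrain only the *normal* component
  (point-to-plane), because full closest-point vectors actively suppress
  tangential stretch on near-cylindrical shapes; and the lattice fit is
  preceded by a per-axis extent match plus a global affine point-to-plane
  ICP. Without the pre-fit, a bone that is simply 5% longer is registered
  with essentially zero correspondence recovery (the surface fits, the
  anatomy slides); with it, known phantom correspondences are recovered to
  well under 2 mm.
* **Volumetric morphing** (`morph_tet_mesh`): the reference tetrahedral
  mesh follows any corresponded surface by solving a Laplace boundary-value
  problem with linear tetrahedral finite elements. Linear FEM reproduces
  affine fields exactly, which the tests verify; the fraction of inverted
  cells is reported.
* **Appearance mapping** (`map_appearance`): each cell takes the HU of the
  voxel nearest its centroid -- no interpolation, by design, so the value
  set of the volume is preserved.

For phantom populations the generator's meshes already share topology, so
the FFD/morph path is optional there (it has its own tests); the
experiment pipeline uses the exact generator correspondence.

## Simulated radiographs

DRRs are computed by absorption-only ray casting: samples every `step` mm
along each ray are converted to opacity with the linear transfer function
`op = 0.25 * HU / 1700` (clamped to [0, 1], non-positive HU transparent),
and composited as $T \mapsto T\,(1 - \mathrm{op}\cdot s/s_\mathrm{ref})$
with reference step 1 mm; the pixel intensity is $1 - T$. The closed-form
intensity of a constant slab is used as the test oracle.

Geometry: anatomical frame x medial-to-lateral, y posterior-to-anterior,
z distal-to-proximal; the AP beam travels along $-y$, the ML beam along
$+x$; image rows run proximal to distal. The default is a perspective
camera with a 1500 mm source-detector distance and the object midway
(magnification 2); a parallel mode is provided and is used for the heavy
test configurations. Target and model are always projected with the *same*
geometry, so metric comparisons are insensitive to this choice.

Defects are simulated on the image, not in 3D: the distal fraction $f$ of
the projected bone rows is set to background and flagged in a validity
mask; exactly `round(f * bone rows)` rows are masked.

## Reconstruction

Given per-view target radiographs, the objective for weights $b$ is:
instantiate, project with the target geometry, extract the silhouette
contour (marching squares at sub-pixel precision on the largest connected
component), pre-align by the most proximal contour point, refine with 2D
rigid ICP, then either

* **contour metric**: mean distance from model-contour points to the
  nearest target-contour segment (one-way by default; the target may be
  truncated by the defect), or
* **intensity metric**: $1 - r$ with $r$ the Pearson correlation of grey
  values after resampling the model image into the target frame.

Model contour points falling in the target's masked rows are excluded
*before* alignment and metric evaluation, so the model is never penalised
for bone the target image lacks -- the only reading under which a 50%
defect reconstruction is well-posed. Multi-view objectives are unweighted
sums.

Optimisation is incremental bound-constrained L-BFGS-B: stage $k$ optimises
the first $k$ weights within $\pm 3$ sd, initialised with the previous
stage's solution padded by zero (stage 1 starts at 0). Two numerical
choices are load-bearing:

* the finite-difference step for the numerical gradient (`fd_step`,
  default 0.05 sd) must exceed the image-discretisation noise of the
  metric; with optim's default $10^{-3}$ the gradient is identically zero
  and the optimiser never leaves the initial guess. Each stage additionally
  runs a coarse-then-fine step schedule (0.15 sd, then `fd_step`): the
  coarse pass sees the large-scale slope through the pixel-scale
  ruggedness, the fine pass polishes;
* each stage has a hard objective-evaluation budget
  (`max_evals * (k + 1)`); line searches on the flat regions of image
  metrics otherwise consume unbounded time. On exhaustion the best
  evaluated weights are kept and the stage is flagged unconverged. Since
  the first evaluation of each stage is the padded previous solution, the
  stage-final objective trace is non-increasing by construction.

The pipeline contains no randomness; all stochasticity lives in phantom
sampling behind explicit seeds.

## Evaluation

`surface_rmse` rigidly aligns the reconstruction to the truth (ICP) and
takes the RMS of vertex-to-surface distances (point-to-triangle);
`hausdorff` is the symmetric maximum under the same alignment, so RMSE
never exceeds it. `compute_measures` reports the six clinical angles and
the head radius:

* femoral anatomical axis: centroids of diaphyseal cross-sections; when the
  mesh carries the phantom family's ring labels the exact mesh rings are
  used, otherwise slabs perpendicular to the iterated axis estimate; the
  axis direction is the least-squares line through the centroids in the
  central 60% of the bone length;
* bow angle: angle between tangents of a cubic fit to the full centroid
  polyline, evaluated at its 10% and 90% stations;
* mechanical axis: head-sphere centre (algebraic least-squares sphere fit)
  to knee centre (epicondyle midpoint);
* neck angle: neck axis (cross-section centroids of the neck region)
  against the distal diaphyseal direction;
* version (PCA/TEA) angles: neck axis against the posterior condylar or
  trans-epicondylar axis, both projected onto the transverse plane, taken
  perpendicular to the anatomical axis;
* diaphyseal-condylar angle: distal condylar axis against the anatomical
  axis.

Extremal condylar landmarks are centroids of vertices within a small band
(1-1.5 mm) of the extreme coordinate, measured in an internal anatomical
frame derived from the mesh itself (shaft principal axis, condyle
centroids). This makes every measure exactly equivariant under rigid
motion -- the tests check invariance to $10^{-6}$ degrees -- and avoids
tie-breaking artefacts at symmetric extremes. Truth and reconstruction are
always measured by the same algorithm, so measure *errors* are unbiased
even where the heuristics have small systematic offsets.

## The phantom generator

The phantom is the minimal shape family that makes all measures
non-degenerate: a tubular shaft swept along a circular sagittal arc (bow),
a conical neck at the neck-shaft angle, rotated about the shaft by the
anteversion angle, a spherical head, and two ellipsoidal condyles whose
extremal points define the condylar axes. All components are generated as
structured tetrahedral solids with fixed topology; the surface mesh is the
tet-mesh boundary, so vertex $k$ corresponds anatomically across any two
phantoms and populations are corresponded by construction.

Conventions worth noting:

* `bow_angle` is *defined* as the tangent turn of the diaphyseal centreline
  between its 10% and 90% stations -- the quantity the automated bow
  measurement reports -- so the constructed arc turns `bow_angle / 0.8` in
  total.
* `neck_shaft_angle` is measured between the neck axis (towards the head)
  and the distal direction of the straight diaphyseal axis; anteversion is
  measured against the posterior condylar axis in the transverse plane.
* The two-compartment density (cortical shell of given thickness over a
  medullary interior) gives the appearance model non-trivial structure;
  voxelization samples the analytic construction directly.

Population defaults (length 430 +/- 25 mm, neck-shaft 127 +/- 5 deg,
anteversion 12 +/- 8 deg, bow 4 +/- 1.5 deg, head radius 23 +/- 2 mm,
cortical 1400 HU / medullary 150 HU, with mild allometric correlations
among the size parameters) are plausible adult values chosen once; they are
configurable but deliberately not tuned to any dataset, since the original
cohort's morphometrics are not public. Draws violating parameter bounds are
resampled, not clipped, to avoid boundary atoms.

What the generator does *not* emulate: trabecular microstructure, cortical
thinning profiles, pathological morphology, soft tissue and overlapping
anatomy in the radiographs, scanner noise and calibration error. A green
test therefore establishes the correctness and internal consistency of the
algorithms, not clinical accuracy on real radiographs.

## What the experiments show at phantom scale

`run_experiment` replicates the study design in miniature: leave-one-out
models, target DRRs at defect levels 0/10/20/50%, contour and intensity
metrics, AP or AP+ML views, one tidy results row per case. With the small
default populations (6-15 specimens, 3 modes, 2-3 mm pixels) leave-one-out
surface errors come out around 1.5-4.5 mm and grow with the defect level;
the acceptance suite asserts only the *ordering* (median RMSE
non-decreasing in defect level), not any absolute magnitude, because
absolute errors at this scale reflect the tiny training sets, not the
method. The self-recovery test (target generated from the model itself)
asserts absolute accuracy: weights within 0.25 sd and RMSE under 1 mm.

## Known limitations

* Projection-direction (pose) recovery is out of scope: targets and models
  are projected in the same known anatomical frame, with only 2D in-plane
  alignment estimated.
* The contour metric is one-way (model to target) by default; the
  symmetric variant is available but is not meaningful on defect-cropped
  targets.
* The FFD correspondence is geometric; on featureless regions (the head
  sphere) correspondence is determined by the smooth continuation of the
  lattice, not by anatomy.
* MetaImage volumes and PGM radiographs are written with plain headers;
  there is no DICOM support, by design.
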