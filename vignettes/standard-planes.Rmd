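---
title: "Estimating and comparing ankle standard planes in 3D C-arm volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing ankle standard planes in 3D C-arm volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contraplane)
```

## The problem

After open reduction and internal fixation of an ankle fracture, surgeons
verify the reduction on an intra-operative cone-beam (C-arm) volume. Because
a mobile C-arm carries no standardized patient orientation, the three
multiplanar reconstruction (MPR) viewing planes must first be adjusted to
the anatomy-specific *standard planes*: the axial plane orthogonal to the
tibial shaft, the sagittal plane bisecting the fibula/tibia contour at talar
dome level, and the coronal plane completing the orthogonal triple. All
three intersect in the middle of the lowermost tibial plafond. Since
intra-individual variation between a patient's two ankles is small compared
with inter-individual variation, the healthy contralateral ankle is a
natural reference: if both ankles are captured in one flat-panel scan, the
two joints can be shown side by side at the same anatomical level.

`contraplane` implements the full computational chain behind such a
comparison:

1. **Localization** — every tibial plateau in the volume is found by
   segmenting an artificial 5 mm sphere landmark with a sliding-window 3D
   U-Net, fusing the overlapping patch predictions by per-voxel mean, and
   clustering the fused probability map with weighted k-means
   (`k` = number of ankles).
2. **Plane estimation** — an ROI is cropped around each detection and a
   second network segments three flat *cylinder* masks (radius 25 mm,
   height 2 mm by default), one per standard plane, with the regions where
   the orthogonal cylinders intersect omitted from the labels. A principal
   component analysis of each class's voxel coordinates recovers the plane:
   the two large eigenvalues span the disc, the eigenvector of the smallest
   eigenvalue is the plane normal, and the mean of the three class centroids
   approximates the intersection point.
3. **Alignment and views** — the two frames are brought to a common
   laterality and axial slices are resampled at three clinical levels:
   talar dome (−6 mm), plateau (0 mm) and tibiofibular incisura (+10 mm)
   along each ankle's own axial normal, with an optional common correction
   offset.

Every stage accepts either a trained network or a ground-truth *oracle*
segmenter, so the geometric machinery is testable in isolation from the
learning component.

## Coordinate and frame conventions

* Voxel indices are 0-based triples in (x, y, z) array order; the world
  coordinate of a voxel is the position of its **center** in millimetres;
  `world = origin + index * spacing`. Only axis-aligned, positively
  oriented NIfTI affines are accepted.
* A standard-plane frame is the intersection point plus the three unit
  normals `n_sag`, `n_ax`, `n_cor`. Signs are anchored to the anatomy:
  `n_ax` points from the plafond toward the proximal tibia, and the
  fibula sits at positive sagittal and coronal offsets. Under this
  convention the handedness `det([n_sag n_ax n_cor])` (+1 right, −1 left)
  *equals the anatomical laterality*, which is how `classify_laterality()`
  works and why no separate laterality detector is needed.
* Because the per-class PCA normals are estimated independently, they are
  generically not exactly orthogonal. `orthonormalize_frame()` projects the
  3×3 normal matrix onto the nearest orthogonal matrix in the Frobenius
  sense (the polar factor of its SVD). This treats the three planes
  symmetrically, unlike Gram–Schmidt, which would privilege whichever
  normal is processed first. Inputs with any pair of raw normals within
  30° of parallel are rejected as degenerate.

A consequence of the anatomy-anchored signs worth spelling out: a left
ankle's frame is itself the mirror image of a right ankle's frame, so
resampling each ankle's axial slice *in its own frame axes* already yields
pixel-wise anatomically corresponding images. The "mirroring to a common
laterality" is therefore carried entirely by the frames; the explicit
in-plane mirror in `build_comparison()` is only applied when the user
switches the display convention (`display_side = "left"` flips both
slices).

## The synthetic phantom

Clinical and cadaveric C-arm scans of this kind are not publicly
available, so the package ships a parametric ankle phantom with *exact*
ground truth.
The template is deliberately minimal:

* a large tube (tibia surrogate, radius 8 mm) along the canonical axial
  direction, terminated by a transverse plateau slab (radius 14 mm,
   3 mm thick) whose lowest central point is the frame intersection;
* a thinner parallel tube (fibula surrogate, radius 4 mm) offset 12 mm
  sagittally and 6 mm coronally;
* a medial-malleolus surrogate (radius 5 mm) on the opposite side,
  extending distally below the plafond;
* an ellipsoid below the plateau (talus surrogate).

The two off-axis landmarks at different azimuths are essential, not
decorative. With a single off-axis landmark (fibula only), a mirrored left
ankle is — up to the talus aspect ratio — indistinguishable from a rotated
right ankle, while the correct frame azimuths differ by tens of degrees;
since both lateralities occur in any realistic dataset, the frame azimuth
would be nearly unidentifiable from the image and no segmenter could learn
it. Two distinct landmarks define a chirality around the shaft that no
rotation can imitate, which is what makes azimuth and laterality learnable
and is also what the sign-orientation probe in the estimation stage relies
on. The malleolus surrogate sits entirely below the plafond so that the
fibula probe region (positive sagittal/coronal offsets above the plafond)
never overlaps it.

`generate_phantom()` scales (uniform in [0.8, 1.2]), rotates (per-axis
Euler angles, applied x-then-y-then-z, uniform in ±45°), mirrors (left
laterality) and translates the template, evaluating the transformed analytic
predicates at voxel centers — there is no resampling step, so the rendered
pose is exact and the returned frames have zero annotation error. Additive
Gaussian noise (default sd 0.05 on a unit-intensity template, a mid-range
detector noise level) stands in for reconstruction noise. Bilateral samples
contain one left and one right ankle with > 60 mm center separation and
≥ 20 mm boundary margins; placements are rejected and resampled until the
margins hold.

Default grids: 64³ voxels at 1.5 mm for unilateral samples and 96×64×64 at
1.5 mm for bilateral ones — the 96 mm extent of a cubic desk grid cannot
hold two intersection points 60 mm apart with 20 mm margins, so the
bilateral grid is wider along x. Training phantoms use 32³ at 2 mm: the
spacing is dictated by sampling, since the smallest template feature (the
4 mm-radius fibula) must span more than one voxel to be visible, and the
cylinder targets must be at least two voxels thick — which is also why the
training masks use a 4 mm height (two voxels at 2 mm, the same thickness
in voxels as the default 2 mm masks at the full-scale 1 mm spacing). What
the phantom deliberately does **not** model:
bone texture, metal implants and artifacts, fractures, beam hardening.
Tests passing on phantoms therefore demonstrate the correctness of the
geometry, clustering, PCA recovery and alignment machinery, and that the
learning recipe can fit a pose-variable anatomy — they do not certify
clinical accuracy on real scans.

`augment()` reproduces the training-time augmentation: per-axis rotation,
isotropic scale, axis mirroring, and offset augmentation realized as random
cropping. Images are resampled trilinearly, labels nearest-neighbor, and
ground-truth frames are transformed analytically rather than resampled.

## Numerical choices

* Mask membership boundaries are inclusive (`<=`), making rasterization
  deterministic; a voxel inside two or more plane cylinders is demoted to
  background whether the overlap is pairwise or triple.
* Patch fusion uses compensated (Kahan) summation, so the fused probability
  map is exactly independent of patch processing order.
* Weighted k-means uses deterministic farthest-point seeding from the
  weight-maximum voxel; assignment ties go to the lower center index.
  Voxels with fused probability ≤ 0.05 are excluded. If the two centers of
  a `k = 2` run land closer than 40 mm they are treated as duplicate
  detections of one ankle and merged with a warning.
* `derive_plane_params()` refuses masks with fewer than 50 foreground
  voxels and warns when `(λ₂ − λ₃)/λ₁ < 0.05` (near-degenerate
  eigenstructure, e.g. an ROI that clips most of a cylinder).
* The intersection point is the unweighted mean of the three per-class
  centroids, which is robust to the unequal class sizes left by the
  omission rule; the pooled-voxel mean is available as
  `intersection = "pooled"`. PCA runs on world-mm coordinates — identical
  to voxel indices for the isotropic grids used throughout, but correct
  also for anisotropic ones.
* Estimated normal signs are fixed from the image: `n_ax` is flipped
  toward the higher integrated intensity (the shaft), then the
  `(n_sag, n_cor)` sign combination is chosen by probing the expected
  fibula position (+10…14 mm sagittal, +5…7 mm coronal, bracketing the
  0.8–1.2 scale range). With signs fixed this way, handedness equals
  laterality on both phantom and, by design, real anatomy.
* Trilinear resampling snaps continuous indices within 1e−9 of a lattice
  point onto it, so identity transforms reproduce their input bit-exactly.

## The segmentation network

The segmenter is a plain 3-level 3D U-Net in the spirit of the original
architecture: two (3×3×3 convolution → instance norm → ReLU) blocks per
level with 8/16/32 channels, 2×2×2 max-pooling, trilinear upsampling with
skip concatenation, and a 1×1×1 output convolution (2 channels for the
sphere localizer, 4 for the plane segmenter). Convolutions are realized as
im2col gathers (compiled code) followed by BLAS matrix products; the
backward pass is hand-derived and verified against finite differences in
the test suite. The loss is the sum of voxel-mean cross-entropy and
`1 − mean` soft Dice over the foreground classes (ε = 1e−5), the standard
combination for extreme foreground/background imbalance; the two terms are
weighted 1:1 by default. Optimization is Adam; training is single-threaded
and bit-reproducible given the seed, and a non-finite loss aborts with
diagnostics. Checkpoints are written as plain JSON (weights at full
precision plus both configs and seeds), so a saved model is a readable,
diffable artifact.

The package default learning rate is 3e-4, a setting appropriate for
full-scale training (hundreds of volumes, 300–1000 epochs ≈ 10⁴ optimizer
steps). The desk-scale experiment exercised in the tests — 40 phantoms of
32³ voxels, batch 4, 20 epochs ≈ 200 steps — is two orders of magnitude
shorter, and at 3e-4 the optimizer cannot move the weights far enough to
lift the foreground Dice off its floor; the schedule, not the model, is the
binding constraint. The desk-scale runs therefore use lr = 3e-3, scaling
the step size roughly with the shortened schedule. Desk-scale augmentation
uses ±15° rotations and 0.9–1.1 scale: the generator already spans the
full ±45° / 0.8–1.2 pose distribution across its samples, so augmentation
only needs to interpolate between the 40 observed poses; composing the
full-strength ranges on top of the generator's would train on poses well
outside the evaluation distribution (package defaults keep the full-scale
ranges). Held-out evaluation (10 unseen phantoms) recovers the frame from
the predicted labels with `estimate_frame()` and reports the
sign-invariant per-plane angular errors. At this problem size the axial
normal and intersection point are recovered reliably (a few degrees, ~2 mm)
while the rotation about the shaft remains the hardest degree of freedom —
its only cues are the two off-axis landmarks, and 200 optimizer steps
leave part of that residual unconverged.

## Evaluation metrics

`frame_errors()` reports `pos` (Euclidean distance between intersection
points), `pos2ax` (distance from the predicted intersection to the **true**
axial plane — the clinically dominant error, since it shifts the displayed
level), and per-plane angular deviations `acos(|n̂·n|)` folded to [0°, 90°].
Angles are sign-invariant because normal orientations are a convention;
`pos2ax ≤ pos` holds by Cauchy–Schwarz and is asserted across the suite.
`summarize_errors()` gives medians (robust to the rare gross failure),
standard deviations both over all cases and over per-group medians (the
cross-validation-style summary), and maxima. On bilateral cases
`evaluate_run()` matches predictions to truths by nearest intersection
point (exhaustive assignment on the 2×2 cost matrix) and counts unmatched
ankles explicitly.

## Problem sizes used by the tests

Mask/oracle equivalence runs on ≈32³ grids; the 100-frame plane-recovery
round trip uses 54³ voxels at 1 mm with the default 25 mm/2 mm masks; the
noise-robustness sweep uses 20 seeds per flip rate in {0, 2, 5, 10}%; the
end-to-end oracle check runs 20 bilateral phantoms at desk scale
(96×64×64 @ 1.5 mm, patch 32 / stride 16 / crop 40); the learning check
trains on 40 phantoms of 32³ for 20 epochs and evaluates on 10 held-out
phantoms. These sizes keep the whole suite reproducible on a single CPU
while leaving every algorithmic path exercised at realistic geometry.

## Known limitations

* The phantom's simplicity means the learning results demonstrate recipe
  correctness, not clinical performance; metal artifacts and fractures —
  the dominant failure modes on real intra-operative scans — are out of
  scope.
* Only axis-aligned image geometry is supported; oblique acquisitions must
  be resampled upstream.
* The number of ankles is user-declared (as in the interactive tool this
  mirrors); there is no automatic instance counting.
* Laterality classification relies on the anatomical sign conventions; on
  anatomy whose fibula/tibia arrangement the conventions do not describe
  (severe deformity), the sign probe can misclassify.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
s <- generate_phantom(phantom_spec(n_ankles = 2, seed = 7))
cfg <- pipeline_config(patch_size = 32, stride = 16, crop_size = 40)
run <- run_pipeline(s$volume,
                    oracle_sphere_predictor(s), oracle_plane_segmenter(s),
                    n_ankles = 2, config = cfg)
summary(run)
frame_errors(run$frames[[1]], s$frames[[1]])
plot(run$views$upper)
```
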