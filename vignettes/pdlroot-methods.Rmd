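---
title: "Ligament-guided root segmentation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligament-guided root segmentation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

On large-field-of-view cone-beam CT (CBCT), dentine and alveolar bone have
overlapping grey ranges, so no single threshold window can separate a tooth
root from the bone that surrounds it. What does separate them anatomically
is the periodontal ligament (PDL): a fibrous layer, roughly 0.15-0.38 mm
thick, between root cementum and bone. At a typical large-field voxel size
of 0.3 mm the PDL is thinner than one voxel; partial-volume averaging
renders it as a faint, *discontinuous* dark shell, so naive use of the
shadow as a separator fails.

`pdlroot` turns that shell into a reliable separator:

1. **Root-bone mask** — threshold the hard-tissue window (dentine + enamel
   + bone together; their separation is exactly what thresholding cannot
   do).
2. **PDL mask** — threshold the dark-shadow window. Both windows are closed
   intervals and may overlap.
3. **Extended PDL mask** — dilate the PDL mask with the full 3x3x3
   structuring element (26-connectivity), 1-2 iterations. This closes the
   partial-volume gaps and restores a *continuous* separating shell. An
   in-plane 8-connectivity variant is kept as an option because it is the
   natural ablation: in-plane dilation cannot close out-of-plane gaps.
4. **Root seed mask** — Boolean-subtract the extended shell from the
   root-bone mask. Every root-bone bridge ran through the shell
   neighbourhood, so the tooth becomes an isolated island.
5. **Manual edits** (optional) — small add/remove corrections for touching
   crowns or residual contacts, applied in order.
6. **Individual root seed mask** — 26-connected component at a per-tooth
   seed point.
7. **Gradient-limited expansion** — regrow the seed to the true root-bone
   boundary (the subtraction removed a shell-wide margin of real tooth).
   A voxel is added when its grey lies in the seed's 1st-99th percentile
   range (widened by `windowSlack`) *and* its gradient magnitude (Euclidean
   norm of central differences, grey units/voxel) is at most `gradCap`; at
   most `maxStep` synchronous rounds run. The gradient cap is what stops
   the region at the root surface even though bone grey is inside the
   window: crossing the shell means stepping through a dark voxel (outside
   the window) or through a steep edge (above the cap).

The expansion semantics are this package's own definition: the commercial
tool the workflow originates from does not document its algorithm, so the
contract here — percentile window, central-difference gradient cap, bounded
synchronous rounds — is stated explicitly and tested against an independent
geodesic-BFS oracle. One consequence worth knowing: with central
differences, voxels whose stencil touches a sharp interface carry a large
gradient, so the final one-voxel rim next to a strong edge is generally not
recovered; sub-voxel accuracy at the surface is recovered at the meshing
stage instead, where the marching isosurface at level 0.5 places the
surface half a voxel outside the mask boundary on average.

## Defaults and their reasoning

* `dilationIters = 2`, 26-connectivity: with a 0.25 mm shell sampled at
  0.3 mm, single-voxel gaps dominate but two-voxel gaps occur at oblique
  incidence; two iterations close both. The spatial (26) extension is the
  default because the in-plane variant misses axially oriented gaps.
* `maxStep = 6`: the subtraction removes at most `dilationIters` + shell
  width of real tooth (3-4 voxels); 6 rounds recover it with margin while
  still bounding any leak through a pinhole to a 6-voxel blob.
* `gradCap` = half the dentine-to-PDL grey drop per voxel: well above the
  interior texture gradient, well below the drop at the root surface.
* `windowSlack` = twice the noise SD; the noise SD can be estimated from
  the volume itself as `mad(Laplacian)/sqrt(42)` (`estimateNoiseSd`),
  since a 6-neighbour Laplacian of i.i.d. Gaussian noise has variance
  42 sigma^2 and the median absolute deviation ignores the structural
  tails.
* Thresholds are user inputs on real data, as in the interactive
  workflow; `suggestConfig()` derives them for phantoms from the known
  tissue greys (hard-tissue window from midway into the dentine-PDL gap,
  shadow window up to that same boundary).

## Evaluation methodology

The extracted mask becomes a triangle mesh (marching tetrahedra at level
0.5 of the binary grid, vertices welded through a global edge map; the
six-tetrahedra cube split is used because it needs no large case table and
is watertight by construction). Smoothing is off by default: Laplacian
smoothing provably shrinks closed surfaces, and the shrinkage would bias
the dimensional errors.

Test and reference models are compared only over the root: a least-squares
plane is fitted to the cemento-enamel junction (CEJ) curve and both meshes
are clipped to the apical side, with straddling triangles split at the
plane. A curve-following cut would track the anatomical junction more
faithfully; the plane approximation is applied identically to both models,
which preserves comparability of the cut parts. Registration is rigid ICP
with point-to-surface correspondences, initialized from centroid +
principal axes (best of the four proper-rotation sign flips, plus the
identity for models that already share a frame) — registration runs on the
cut root parts, because the reference model has no crown and
whole-model correspondences would drag the test mesh apically.

Deviation is the root-mean-square of unsigned nearest-point distances,
`RMS = sqrt(sum(Xi^2)/N)`, sampled at the test-model vertices (all of them
up to 10,000, a seeded uniform subsample beyond; reference models in the
validated workflow have on the order of 7,000 vertices, so sampling is
typically exhaustive). Signed distances (sign from the nearest triangle's
normal) are exported for the familiar +-0.6 mm colour maps. The measure is
directional by construction; the test-against-reference direction is the
one reported.

Dimensions are measured in a per-tooth frame: Z along the first principal
component of the vertex covariance (oriented apex-negative by the centroid
offset toward the bulky coronal end), X the bucco-lingual direction from a
user hint projected orthogonal to Z (second principal component otherwise),
Y completing the right-handed triad. BL/MD/RL are vertex-projection extents
along X/Y/Z, and errors are reference minus test, so negative means the
extracted model is too large.

## The synthetic phantom

The generator builds an analytic scene in mm: the root is the convex hull
of an apex sphere and a CEJ sphere (a "round cone", exact signed distance)
capped by the CEJ plane; two-rooted teeth use two divergent cones under a
shared crown; the crown is an enamel ellipsoid; the PDL is the true metric
offset shell of the root (0.25 mm by default, inside the anatomical
0.15-0.38 mm range); alveolar bone is a slab with the socket carved out at
shell thickness, its crest 1.5 mm below the CEJ. Dentine grey ramps
linearly from apex (1100) to CEJ (1250) across bone grey (1150) — the
crown-to-root density gradient plus the dentine/bone overlap that motivates
the whole approach. Grey levels are 12-bit-like stand-ins chosen once for
their ordering and overlap structure; no quantitative CBCT grey calibration
exists to reproduce.

Rasterization averages `supersample`^3 (default 27) analytic samples per
voxel — a box-filter partial-volume model, chosen over analytic convolution
for controllability — then adds i.i.d. Gaussian noise (SD 40) from a seeded
generator. This reproduces the decisive imaging property: the sub-voxel
shell appears as an intermittent shadow whose threshold mask is
disconnected (a tested invariant). What the phantom does *not* model:
beam hardening, scatter, metal artifacts, detector MTF, anisotropic noise,
neighbouring teeth, and anatomical surface texture. Passing the phantom
validation therefore demonstrates the *mechanism* — separation via the
dilated shell, sub-voxel surface recovery — not clinical-grade accuracy on
patient scans.

Ground truth is three-fold: voxel-centre membership masks, the analytic
root surface meshed from the exact signed-distance field at half-voxel
resolution, and the CEJ silhouette curve. The truth mesh plays the role of
the scanned extracted-tooth reference model.

## Validation experiment and problem sizes

`runValidation()` generates a seeded batch of phantoms (default anatomy in
a 128^3 grid at 0.3 mm), runs the full pipeline per case, and reports
per-case RMS, root-region Dice (final mask against the truth tooth over
voxels apical to the CEJ — the root is the clinical object of interest and
the crown is cut away in the mesh evaluation too), and BL/MD/RL errors. At
these sizes the five-case batch completes in about a minute on one core.
Observed behaviour under the default conditions: RMS around 0.17 mm
(comfortably inside the one-voxel bar of 0.3 mm), Dice around 0.93, and a
root-length error of well under a voxel. Under unlucky noise realizations
a pinhole can open in the thresholded shell and the expansion then picks
up a small bone blob (bounded by `maxStep` to a few dozen voxels; observed
RMS up to ~0.28 mm); the per-stage log and the bone-overlap count make
such cases visible. The companion ablation
(`separationAblation`) re-runs the mask stages with 0 dilation iterations
and counts bone voxels in the seed component: with dilation the overlap is
zero, without it the component floods into bone — the mechanism made
visible. Unit tests use scaled-down scenes (48-64 voxel grids with a
proportionally smaller tooth) so the whole suite stays fast; the
oracle-equivalence suites run on randomized grids up to 10^3 voxels.

## Numerical choices and degenerate inputs

* Closed-interval thresholds: both bounds inclusive, so window edges are
  testable exactly.
* Dilation of an empty mask, `iterations = 0`, `maxStep = 0`, empty edit
  lists: all identities; empty seeds, empty meshes, all-zero paired
  differences: errors with specific messages.
* A CEJ plane that misses both meshes warns and returns them uncut.
* Exact Wilcoxon p-values (n <= 15 after zero-drop) come from the full
  sign-flip distribution via a dynamic program over doubled ranks, which
  remains exact under ties; larger n uses the tie-corrected normal
  approximation. The Bonferroni post-hoc uses the pooled ANOVA mean square
  error with N - k degrees of freedom (the convention of the statistics
  package used for the published tables; per-pair Welch tests would not
  reproduce them).
* Sample SD uses the n-1 denominator throughout.
* The one-sample K-S normality test plugs in the sample mean/SD; the
  Lilliefors-corrected variant is available behind a flag. Which variant
  the original analysis used is not documented, so no specific
  normal/non-normal split is asserted.
* NIfTI geometry is stored in float32 by the format; round-trips are exact
  for voxel data and accurate to ~1e-7 for spacing/origin. STL writing
  quantizes vertices to float32 before computing facet normals so that a
  write-read-write cycle is bit-identical.
* DICOM support is deliberately minimal (uncompressed little-endian,
  single-frame, axial): enough for series exported by scanners in the
  validated workflow; anything else is rejected loudly rather than
  reformatted.

## Known limitations

* The CEJ cut is planar, not curve-following.
* Signed distances use the nearest facet's normal, which can misclassify
  the side exactly on sharp edges; unsigned distances (the RMS input) are
  unaffected.
* Seeds are explicit world points; there is no automatic tooth detection.
* The phantom's bone is homogeneous; real trabecular texture makes window
  selection harder than the generator suggests.
* Grouping of the packaged 20-root table into single- versus double-rooted
  teeth is not recoverable from the published data, so subgroup analyses
  are out of scope.
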