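---
title: "fracture3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fracture3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `fracture3d` computes, the assumptions behind
each stage, the parameters that matter and why their defaults are what they
are, and where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The pipeline

A CT series is an ordered stack of axial slices; each DICOM header carries
the image matrix size, the in-plane pixel spacing (mm/pixel), the slice
thickness (mm), and the linear rescale (`slope`, `intercept`) that converts
stored integers to Hounsfield units (HU). The pipeline is:

1. **Ingest** (`readDicomSeries`): slices sorted by position along the scan
   axis (ImagePositionPatient z, falling back to SliceLocation, then
   InstanceNumber — the stack must be ordered but headers differ in which
   key they populate), voxels rescaled to HU.
2. **Segment** (`thresholdBone`): binary mask of voxels whose HU lies in a
   closed cortical band, default [1150, 1250].
3. **Reconstruct** (`extractSurface` + `capMesh`): triangulated isosurface
   of the binary mask in mm coordinates, capped into a watertight solid.
4. **Detect** (`detectRule` / `detectYolo`): per-slice 2D fracture boxes in
   the 4-tuple convention `(x_start, y_start, x_extent, y_extent)`.
5. **Map** (`boxToCuboid` + `stackMask` + `overlayScene`): boxes lifted
   into physical cuboids and rendered as a translucent red mask over the
   bone mesh.
6. **Evaluate** (`matchDetections`, `prCurve`, `iouStats`): IoU-based
   matching, precision/recall, PR curve, average precision, IoU mean/SD.

### Coordinate conventions

One set of conventions is used everywhere, because most errors in this kind
of pipeline are convention mismatches:

* Voxels are indexed `(row, col, slice)`, 0-based in all public interfaces.
  Rows run down the image (image Y), columns run right (image X).
* Boxes are half-open in pixel index space: a box covers columns
  `[x_start, x_start + x_extent)`, so its area is exactly
  `x_extent * y_extent` pixels. This makes pixel-counting IoU exact and
  integer.
* The physical frame is the scanner grid: origin at the corner of voxel
  (0, 0, 0), axes along image X, image Y and the slice direction; a vertex
  at voxel index `i` maps to `i * spacing` mm. A box on slice `k` occupies
  the half-open z-slab `[k t, (k+1) t)`. The full DICOM patient frame
  (ImageOrientationPatient) is deliberately ignored: the pipeline treats
  axial stacks, and a non-axial orientation would be logged, not silently
  reinterpreted.
* Under these conventions the lift `box -> cuboid` is exactly invertible,
  and the voxelized volume of disjoint cuboids equals the sum of
  `dx dy dz` with no discretization error — both are tested.

## Segmentation and reconstruction

**HU band.** The cortical band is closed on both ends, `[1150, 1250]` by
default. A two-sided band reads most plainly as inclusive; whether the
upper bound is meant to exclude denser cortical bone is genuinely
ambiguous, so both bounds are plain configuration values
(`thresholdBone(volume, hu_low, hu_high)`), and thresholding is monotone in
the interval by construction.

**Isosurface.** The surface is extracted by marching tetrahedra at
iso-level 0.5 of the binary field: each cell between eight voxel centres is
split into six tetrahedra around a fixed diagonal, surface vertices sit at
edge midpoints, and triangles are oriented outward (checked against the
inside-to-outside direction at emission time). The decomposition is
consistent across shared cell faces, so the surface of a zero-padded field
is watertight by construction. The field is padded laterally (rows and
columns) only, so bone touching the image border closes in-plane while the
axial ends stay open — exactly the openings that capping then closes.

**Capping.** `capMesh` recomputes the surface with the axial boundary also
treated as background, which closes the top and bottom with planar caps at
half a slice beyond the first/last slice planes. Two useful properties fall
out of this construction rather than being patched in afterwards: a mesh
that was already closed is returned bit-identically (the added padding
cells are empty and contribute nothing), and the capped mesh always passes
the edge-manifold check (every edge shared by exactly two faces). If that
check ever failed it would be reported, not silently accepted.

**Small components.** Connected components below `min_component = 20`
voxels are dropped with a message. Thresholding noise produces specks that
a surgeon-facing rendering would never show; 20 voxels (≈13 mm³ at typical
spacing) is well below any fragment of clinical interest but large enough
to kill isolated noise voxels.

**Volume checks.** Enclosed volume is computed by the divergence theorem
over the oriented triangles. A solid cube of `n³` voxels meshes to within
5% of its analytic volume (the marching surface chamfers edges and
corners); blob volumes agree with voxel-count × voxel-volume within 10%
for blobs of at least 10³ voxels. Both tolerances are asserted in the
tests at exactly those sizes.

## The phantom generator

The generator emulates the geometry that drives every downstream stage: a
tubular bone with a cortical shell in the segmentation band, embedded in
soft tissue and air, fractured at known slices. Defaults (one 512 × 512 ×
40 series, 0.8 mm pixels, 1 mm slices, outer/inner shell radii 20/13
pixels ≈ 16/10.4 mm, cortical level 1200 HU, soft tissue −50 HU, air
−1000 HU, truncated Gaussian HU noise with SD 10) are chosen once to be
representative of an extremity CT and are not tuned per test: 512 × 512 is
the ubiquitous CT matrix and matches the detector's default input size,
and the radii give a tibia-like shaft cross-section at 0.8 mm spacing.

Two fracture types are modelled. A **gap** removes an angular wedge of the
shell (the cortical interruption a fracture line produces in-plane); a
**displacement** translates the whole ring transversely (a displaced
fragment). The ground-truth box on each affected slice is the tight
bounding box of the symmetric difference between the fractured and
unfractured shell masks. Hand-drawn clinical annotations have no
reproducible definition, so a surrogate is required; the symmetric
difference is the minimal region in which the image actually changed, and
it makes the ground truth a deterministic function of the spec.

Noise is truncated at 3 SD so that, at the default level, it can never
carry a soft-tissue voxel into the cortical band or a cortical voxel out of
it (the band edges are 50 HU from the cortical level; 3 × 10 = 30 < 50).
Thresholding a phantom therefore recovers the generator's shell mask
exactly — the oracle behind the reconstruction tests. Setting
`noise_sd = 0` gives the noiseless phantoms used for exact end-to-end
recovery checks.

**What the phantom does not emulate:** trabecular texture, anatomically
shaped bones, partial-volume blurring at the cortex boundary, beam
hardening or metal artifacts, and neighbouring bones in the field of view.
Consequently, passing the phantom suite demonstrates that the geometry,
bookkeeping and metrics of the pipeline are correct; it does not
demonstrate detection performance on patient data, which depends on a
trained network and clinical image character.

## Detectors

**Rule detector.** Per slice: threshold to the cortical band, fit a circle
to the shell pixels by linear least squares (Kasa fit — robust to an
interrupted ring because all pixels contribute), bin shell pixels by polar
angle around the fitted centre with about one bin per pixel of
circumference, and report every circular run of empty bins with arc length
≥ `min_gap_px` (default 5 px) as a cortical interruption. The emitted box
is the bounding box of the annulus sector spanned by the gap (radial range
taken from the observed shell radii); the score is the gap's fraction of
the circumference, so larger defects rank higher. The detector is
deterministic and invariant to any HU perturbation that never crosses the
band. It presumes one roughly convex shell per slice — adequate for the
phantom geometry it is meant to exercise, and explicitly not a clinical
detector.

**Network scaffold.** The one-stage detector follows the published layout:
a CSPDarknet-53 backbone whose five CSP blocks have 1, 2, 8, 8, 4 internal
units and output channels 128, 128, 256, 512, 1024 (spatial size halving
per block, so a 512 × 512 × 3 input yields 256×256×128 down to
16×16×1024); inside each block, convolution → batch normalization → mish.
The neck is SPP (stride-1 max pools at 5, 9, 13 over the deepest map) plus
a PAN with top-down and bottom-up paths; three heads emit
`3 × (5 + classes)` channels. The input size is not stated alongside the
block shapes, but 256 × 256 after one halving forces 512 × 512; it is a
configuration value with that default. Convolutions are computed as
im2col + GEMM in C++; a full backbone forward at 512 px takes on the order
of a minute on one CPU, which is what the shape-contract checks use.

**Toy training.** `trainYolo` runs the published recipe — ADAM, initial
learning rate 0.001, halved every 20 epochs
(`lr(e) = 0.001 · 0.5^⌊e/20⌋`), at most 50 epochs, minibatch 4 — but
updates only the final 1×1 head convolutions, with the backbone and neck
frozen at their seeded initialisation and their features cached per image.
The raw head maps are linear in those weights, so the gradients are exact
(sigmoid cross-entropy for objectness/class, squared error on raw box
parameters at assigned cells). Full backpropagation through a 53-layer
backbone is out of proportion for a desk-scale package whose training
contract is a decreasing loss on toy phantom sets; the transfer-learning
split keeps the optimiser, schedule and loss structure real while keeping
an epoch at toy input sizes in seconds. Anchors default to the standard
9-anchor layout scaled to the input size, and NMS uses IoU 0.5 — neither
is specified by the architecture description, so both are configuration
values.

## Evaluation

Matching is the conventional detection protocol: predictions in descending
score order (stable for ties), each claiming the unmatched ground-truth
box of highest IoU on its slice provided IoU ≥ `iou_min` (default 0.5, the
usual compliance threshold). Unclaimed predictions are FP, unclaimed truths
FN. TN is tracked but enters no metric — it has no meaning for detection.
Degenerate ratios are defined as 1 with a message (no predictions asserted
nothing; no ground truth means nothing was missed), so empty-phantom runs
produce clean reports instead of NaN.

The PR curve sweeps every distinct score as a threshold, recomputing the
matching at each. Average precision defaults to the all-points
interpolation (area under the monotone precision envelope), with the
11-point variant as a switch, since published AP values do not always say
which definition produced them. The IoU summary uses the sample (n − 1)
standard deviation; a single match reports SD 0 with a warning rather than
aborting a small run. Whether IoU statistics should cover matched pairs
only or count unmatched truths as zeros is unstated in most protocols;
matched-pairs-only is the default here because the SD of a mixture with
structural zeros measures miss rate, not localisation quality.

All three metric paths are verified to 1e-9 against brute-force oracles
(pixel-counting IoU on materialised grids, a naive matcher, exhaustive
threshold enumeration) on 200 random instances, and the greedy matcher is
additionally checked never to exceed the optimal assignment computed by
exhaustive enumeration on instances with ≤ 4 boxes per slice.

## Mapping and rendering

`stackMask` groups lifted cuboids whose pixel boxes overlap in-plane and
whose slices lie within `merge_gap + 1` of each other; with the default
`merge_gap = 1` a single-slice detector miss does not split one fracture
into two components, while `merge_gap = 0` merges only directly adjacent
slices. The scene is written as self-contained glTF 2.0 (embedded base64
buffer; bone-coloured opaque mesh, one semi-transparent red box mesh per
component) and the snapshot as an orthographic z-buffer rendering along a
configurable axis with the red mask alpha-blended where bone does not
occlude it — fully deterministic given the camera setting, with no display
device involved.

## DICOM support

The reader/writer covers single-frame Explicit-VR-little-endian CT series
— exactly the subset the pipeline touches (Rows, Columns, PixelSpacing,
SliceThickness, rescale, instance/position, 16-bit PixelData). The writer
emits deterministic UIDs derived from the series geometry so reruns are
byte-identical. Absent rescale tags are treated as slope 1 / intercept 0
with a warning (common in synthetic fixtures); absent spacing or thickness
is an error, because the 3D mapping would be meaningless without them.
Multi-frame files, compressed transfer syntaxes and non-axial acquisitions
are out of scope. The round trip is exact on integer HU volumes and is
cross-checked in the tests against an independent DICOM implementation.

## Problem sizes in the checks

Unit tests run phantoms of 48–96 px in-plane with 6–20 slices and network
inputs of 64–256 px — sizes chosen so the whole suite exercises every code
path in about two minutes. The end-to-end recovery check uses ten full
512 × 512 × 40 noiseless one-fracture phantoms, and the backbone shape
contract runs a real 512-px forward pass. These sizes are the package's
own test design, documented here so results are interpreted at the scale
they were computed.

## Known limitations

* The rule detector finds cortical gaps in single-shell cross-sections; it
  does not handle multiple bones per slice, incomplete rings at epiphyses,
  or displacement-only fractures (an intact displaced ring has no gap).
* Toy training adapts only the head; it cannot learn features, and no
  claim is made about detection quality beyond the phantom geometry.
* The fracture mask is a union of axis-aligned cuboids — it localises the
  fracture region, not individual fragments.
* Meshes are unsmoothed by design; smoothing is available nowhere in the
  pipeline because it can visually close exactly the fracture lines the
  overlay is supposed to reveal.
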