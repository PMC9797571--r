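---
title: "Methods: microcrack network analysis in micro-CT tooth volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcrack network analysis in micro-CT tooth volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toothcrack)
```

## The problem

X-ray micro-computed tomography resolves the microcrack (MC) network of an
extracted tooth in three dimensions: a 16-bit attenuation data-cube at a
few micrometres per voxel in which enamel is bright, dentin darker, and
air, pulp and cracks are all near-black. Because cracks, pulp and outside
air share grey values, simple thresholding cannot isolate cracks; the
working recipe is per-slice voxel *classification* into four classes
(crack, enamel, dentin, air), repeated along all three axes, followed by a
consensus vote. This package implements that chain — phantom generation,
tile-based slice classification, three-axis voting, crack-free fill-in,
connected-component isolation, morphometry, slab/sector partitioning, and
closed-form fracture-mechanics estimates — with every stage testable
against synthetic teeth with known ground truth.

## Conventions

Volumes are rank-3 arrays in `(z, y, x)` order with `z` the vertical tooth
axis, isotropic voxel pitch in micrometres, grey values in the unsigned
16-bit range. Label codes are fixed: 0 air, 1 enamel, 2 dentin, 3 crack
(`label_codes()`); the pulp cavity is air (the four-class scheme has no
pulp class). Grey volumes persist as unsigned 16-bit (TIFF stacks or raw
NRRD), label volumes as unsigned 8-bit. Anisotropic input is rejected
rather than silently resampled. Slab intervals are half-open with
remainder slices assigned bottom-up (cervical first).

## The synthetic tooth phantom

`phantom_spec()` describes a premolar-like crown at desk scale:

* **Grid and pitch.** Default 128^3 voxels at 50 um (6.4 mm extent). Real
  scans are ~2000^3 at 5 um, resampled to ~10 um for analysis; the phantom
  keeps the anatomy at true size on a coarser grid, so one phantom voxel
  plays the role of several scan voxels. Tests use 48-96^3 grids with the
  pitch scaled to keep the tooth at true size.
* **Geometry.** The crown outer surface is a half-ellipsoid with unequal
  horizontal radii (2.7 x 2.2 mm), which gives the convex buccal/palatal
  versus flatter contact-surface asymmetry that sector detection relies
  on. The enamel shell thickness interpolates linearly from 0.5 mm at the
  cervical base to 2.5 mm at the cusp. The pulp chamber is a gently
  tapering, flat-topped cavity (chamber plus canal) that opens through the
  cervical base plane; a pointed apex would narrow below the resolvable
  width, which real pulp chambers do not.
* **Densities and grey mapping.** Enamel 2.61-2.77 g/cm^3 (denser toward
  the outer surface), dentin 1.79-2.12 g/cm^3 (denser toward the
  dentin-enamel junction). Grey is linear in density with mean enamel
  mapped to 60% of the 16-bit range; only the ordering matters downstream.
* **Crack network.** Primary cracks are planar slabs that all contain the
  tooth axis — the star-shaped connected network seen in real teeth — in
  two nearly perpendicular azimuth families (each plane jittered up to
  ±7°; exact lattice alignment is both unrealistic and numerically
  degenerate, because a plane lying exactly between voxel columns has no
  voxel at sub-voxel widths). Isolated disc cracks are biased toward the
  outer surface. By default the connected network is sized to occupy 2% of
  the tooth (hard tissue + crack voxels), the fraction reported for real
  teeth: the solver first fixes the plane width at the thinnest value that
  labels an unbroken one-voxel sheet, then adjusts width (upward) or the
  planes' horizontal reach (downward) by bisection until the labelled
  fraction matches the target. Width sampling defaults to 0.3-30 um when
  no target fraction is requested; at desk-scale pitches most of that
  range is sub-voxel and rendered purely as partial volume.
* **Truth labelling.** A voxel is labelled crack when its crack occupancy
  is at least 0.5 — equivalently, when the rendered grey dips to half the
  local tissue value or below. Thinner cracks still darken their voxel
  (partial volume) but stay below the labelling threshold; the width
  module flags all widths at or below one voxel as sub-resolution.
* **Noise and artifacts.** Additive Gaussian noise (default sd 1500 grey
  units, about 5% of the dentin level — published scans report no noise
  figure, so this is a plausible, not calibrated, choice); optional
  scan artifacts (a zeroed vertical cylinder; radial "rays" above the
  crown). No beam hardening or reconstruction physics.

Phantoms are bit-reproducible for a fixed `rng_seed`, and a spec with no
cracks generates the voxel-exact crack-free twin of a cracked phantom —
the reference for fill-in tests.

## Slice classification

`segment_axis()` classifies every slice perpendicular to x, y and z.
Slices can be cut into overlapping square tiles (`make_tile_grid()`;
origins stride by half a tile and the last tile is clamped flush with the
edge); overlapping probabilities are averaged before the argmax, an
order-independent rule. By default each slice is processed as one tile,
which suits context-dependent backends. Greyscale tiles are replicated to
three channels for the network input.

Two backends satisfy the classifier contract (per-pixel probabilities over
the four classes, summing to 1):

**The reference CNN** is a small dilated-context encoder-decoder written
directly on Armadillo linear algebra: two 3x3 convolution + pooling
stages, dilated 3x3 convolutions (rates 2 and 4) at quarter resolution for
context (receptive field ≈ 59 px), nearest-neighbour upsampling, a
full-resolution skip connection, and a 1x1 softmax head (~20k weights).
Training follows the reference recipe: Adam, batch size 5, categorical
cross-entropy, random contrast (±20%), flips and k·90° rotations, up to 50
epochs. The published configuration's learning rate of 1e-5 is scaled to
1e-3-2e-3 here: this network is four orders of magnitude smaller than a
ResNet50-backbone segmenter and trains from scratch, so the step size
scales accordingly. Training is exactly reproducible for a fixed seed
(single-threaded, R RNG for initialisation, shuffling and augmentation).
On 200 phantom tiles of 64 px the classifier reaches ≥ 99.5% held-out
pixel accuracy in a few minutes on one CPU.

**The thresholding oracle** (`rule_based_oracle()`) is the deterministic
reference backend. Air/dentin/enamel separate by two grey thresholds. The
crack class needs more care, because cracks, pulp and outside air share
grey values:

* a pixel is *low* relative to its surroundings when its grey is below
  half the local tissue reference, recovered by a grey-value closing
  (radius 3) — an absolute threshold would miss partial-volume cracks in
  enamel, whose grey dips only to half the enamel level;
* it must be *enclosed*: not reachable from the slice border after a
  binary closing of the tissue mask seals narrow crack mouths at the
  surface;
* it must run *between tissue walls* (tissue within 4 px on both sides
  along some principal direction) — this rejects the sealed surface
  notches just outside the tooth;
* wide enclosed dark areas that survive a square opening (radius 2) are
  the pulp cavity, not cracks; cavity-adjacent dark pixels are kept as
  crack only when their dark line continues away from the cavity (a crack
  piercing the wall does, a tangential cap of the cavity wall does not);
* partial-volume shoulders adjacent to a detected crack are reassigned
  from a tight (radius-2) closing reference, since their mixed grey
  otherwise downgrades enamel to dentin.

On noise-free phantoms this oracle reaches ≥ 99.7% per-slice accuracy and
per-class voxel counts within 2% of truth along each axis.

## Consensus, fill-in

A voxel is crack when at least two of the three axis labellings say crack
(`vote_crack()`). This vote is what disambiguates the pulp: z-slices see
the pulp as an enclosed dark region (one crack-leaning vote at most), but
in x- and y-slices the cavity opens through the cervical base and reads as
air. Remaining voxels take the majority non-crack code with ties broken by
the z label, then y, then x (z is the primary training orientation; no
published tie rule exists, so one had to be fixed).

`fill_in()` reconstructs the tooth "as if it had no cracks": per z-slice
the crack mask is dilated (default radius 1, 3x3 square) and each masked
pixel inside the tooth takes the code of its nearest non-masked enamel or
dentin pixel (exact Euclidean nearest-site transform). Fill-in operates on
the categorical map, not grey inpainting: nearest-label assignment is
well-defined on categories and exactly testable. It never fabricates
tissue into air, changes nothing outside the dilated mask, and is
idempotent.

## Morphometry

* **Components.** 26-connectivity by default (thin oblique sheets fragment
  under 6-connectivity); ids ordered by decreasing size, ties by smallest
  linear voxel index, so results are deterministic. The size filter
  default of 27 voxels removes single 3^3 noise blobs; the source work
  states no threshold.
* **Volume fraction** divides by tooth voxels = enamel + dentin + crack.
  Whether the reported "~2%" denominator includes the pulp is not stated
  in the source; hard tissue + crack is used and documented here.
* **Local width** is the porous-media local thickness: twice the radius of
  the largest inscribed sphere covering each voxel, from the exact
  Euclidean distance transform with the radius pulled back half a voxel to
  the tissue interface (so a 3-voxel slab at 10 um pitch reads 30 um, not
  40). Widths at or below one voxel are flagged sub-resolution.
* **Orientation modes.** Local plane normals come from the structure
  tensor of the Gaussian-smoothed (sigma 2) crack indicator. For a
  sheet-like structure the normal is the *dominant* eigenvector of the
  smoothed gradient outer product; the smallest-eigenvalue convention
  applies to point-covariance tensors (used for per-component descriptors)
  but not to the gradient tensor. Normals are folded onto the upper
  hemisphere and binned on a 36 x 18 azimuth-elevation grid (648 cells);
  the two strongest modes at ≥ 25° separation and their mutual angle
  summarize the plane families. Two perpendicular phantom planes are
  recovered at 90° ± 5°.
* **Planarity** is `(lambda2 - lambda3) / lambda1` of the component
  covariance eigenvalues: near 1 for sheets, near 0 for threads.

## Slab/sector partition

The tooth's z-extent splits into three equal-height half-open slabs
(cervical, middle, occlusal), remainder slices bottom-up. Per slab, the
mid-slab slice's boundary is traced as a polar radius profile about the
centroid and fitted with a 6-harmonic Fourier series; boundary-pixel
quantization makes finite-difference curvature useless, while the global
fit gives smooth analytic curvature. Transitions between convex (buccal,
palatal) and flatter (contact) arcs are the four crossings of the
curvature through its median (the steepest four, if more); the two chords
connecting opposite transitions split the slab into four sectors, named by
the cardinal direction of each region's centroid (x toward palatal, y
toward the contacts). Chords are computed once per mid-slab slice and
propagated through the slab — stabler than per-slice chords. A
near-circular section (relative harmonic amplitude < 3%) has no robust
transitions and falls back to centroid-anchored ±45° quadrants, flagged in
the output. The "dashed lines" of the original figures are drawn by eye
and 2-D; per-slab 2-D chords are this package's deterministic rendering of
them.

## Fracture mechanics

The Discussion-style closed forms are implemented in SI units with
toughness accepted in MPa·sqrt(m): stress concentration
`sigma_max = 2 sigma sqrt(l_c / l_rho)`; theoretical strength
`sigma_th = sqrt(gamma E / a0) ≈ E / (2 pi)`; critical stress
`sigma_c = K_Ic / sqrt(pi l)` for a linear crack front and `pi/2` times
that for an elliptical front (the elliptical criterion is inverted as
printed, although the "smaller by 2/pi" factor applies to K); the Griffith
form `sigma_c = sqrt(2 gamma E / (pi l))`; bite pressure `m g / area` with
`g = 10` by default, matching the order-of-magnitude convention of the
100 kg / 1 cm^2 → 1e7 Pa estimate. Enamel toughness defaults are
K_Ic⊥ = 1.24 and K_Ic∥ = 0.70 MPa·sqrt(m); surface energy and the
intra-atomic spacing have no agreed enamel values and remain user inputs.
Note that evaluating the formula at K_Ic⊥ and l = 2 um gives 0.49 GPa; the
frequently quoted "≈ 4.9 GPa" for this case is an order of magnitude
larger than the formula's value, and the 0.2% bite-pressure ratio is
computed against that quoted 4.9 GPa figure.

## What the phantom tests do and do not show

Phantom cracks are clean planar slabs with sharp walls, additive Gaussian
noise and exact labels. Real cracks curve, branch, vary in width along
their extent, pass lamellae and tufts, and real scans add beam hardening,
ring artifacts and reconstruction noise that the phantom does not emulate.
Passing the phantom suite therefore shows the chain is *correct* (each
stage does what it claims, with known recovery error under the stated
conditions); it does not certify accuracy on clinical scans, for which the
CNN backend would need real labelled tiles.

## Problem sizes and determinism

Unit tests run on 48-96^3 phantoms; study-scale checks (classifier
accuracy, per-axis census, volume-fraction recovery) use the default 128^3
geometry. Classifier checks train on 50-200 tiles of 64-96 px. All
randomness flows through explicit seeds (phantom `rng_seed`, tile `seed`,
`train_config()$seed`); every pipeline run records its configuration in a
provenance JSON and is reproducible from it.
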