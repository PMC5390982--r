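---
title: "Extracting endocranial surfaces from CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting endocranial surfaces from CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The endocast — the cast of the endocranial cavity — is the standard proxy for
brain morphology in physical anthropology: soft tissue does not fossilize,
but the braincase does, and CT scanning recovers its interior
non-destructively. Turning a CT volume of a cranium into a clean triangle
mesh of the *endocranial* surface is, however, tedious by hand: the
endocranial and exocranial isosurfaces lie millimetres apart, and
slice-by-slice contouring of hundreds of slices is error-prone. `endocast`
automates the extraction. The driving observation is that the endocranial
cavity is (normally) the largest empty space *enclosed by bone*, which makes
it identifiable from the distance field of the bone mask without any manual
seed.

The pipeline has three stages, orchestrated by `run_pipeline()`:

1. **Binarization and void filling** (`threshold_binarize()`,
   `fill_cavities()`). Voxels with CT number at or above an isovalue $t$
   become bone. Small voids inside the bone — the diploic (spongy) layer,
   post-mortem cracks — are then filled by morphological closing with a ball
   structuring element of radius $r$; equivalently, the black-hat set
   (closing minus input) is added to the mask. Without this step those voids
   would register as empty space and distort the segmentation.
2. **Watershed segmentation on the distance field**
   (`euclidean_distance_transform()`, `border_seeds()`, `endocast_seed()`,
   `marker_watershed()`). The exact Euclidean distance $d(\cdot)$ from every
   background voxel to the nearest bone voxel is computed in millimetres
   (anisotropic spacing respected). Every background voxel on the image
   border is seeded "other", together with all voxels within $s\,d(b)$ of
   each border voxel $b$ (a scaling factor $s < 1$ guarantees these balls
   can never cross bone). The remaining global maximum of $d$ must then be
   the cavity centre; it and its $s\,d(e)$-ball are seeded "endocast".
   Priority flooding over the 26-neighborhood, claiming voxels in order of
   decreasing $d$, partitions all background into the two regions, with the
   boundary settling across the distance saddles of the openings (foramina).
3. **Masked polygonization** (`mask_fill()`, `masked_marching_cubes()`).
   "Other" voxels are filled to one quantization step above $t$, so the
   endocast air region becomes completely surrounded by solid values; the
   isosurface at $t$, extracted only over lattice cells touching the
   endocast region, is then a closed two-manifold triangle mesh in
   millimetres, sealed flat across the openings.

For crania whose endocast is *not* the largest enclosed space (small
primates, broken specimens whose braincase communicates widely with the
exterior), the alternative `threshold_seeds()` binarizes the distance field
at a threshold $\hat t$; components of $\{d \ge \hat t\}$ touching the image
border become "other" and the largest interior component becomes the
endocast. $\hat t$ should exceed the distance radius of every bottleneck
connecting to the endocranial space — values of order 10–15 mm are typical
for small primate crania.

## Parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `threshold_t` | CT number | none (required) | bone/air isovalue; any value well inside the air–bone intensity gap gives the same binary mask, and the extracted surface moves by well under a voxel pitch across the middle half of the gap |
| `se_radius`, `se_unit` | voxels (or mm) | 6 voxels | ball radius for void filling; it must exceed the half-width of the voids and cracks to bridge, and stay below the inscribed radius of the cavity itself (a closing ball that does not fit inside a cavity fills it) |
| `seed_scale_s` | – | 0.9 | seed-ball scaling; any $s<1$ is safe, larger values blanket more exterior so the residual maximum falls inside the cranium |
| `distance_threshold_mm` | mm | off | $\hat t$; presence switches to the alternative seeding mode |

In automatic mode only the isovalue and the void size need thought — the
two-parameter operation the method is designed around.

Only `s` needed a choice the problem statement leaves open: we default to
0.9 because the exterior residual maximum after border seeding scales with
$(1-s)$ times the local border distance, and 0.9 keeps that residual (about
3.5 mm on a 64 mm domain) safely below the distance radius of any cavity of
interest. The value is exposed in the configuration.

## Numerical and algorithmic choices

**Exact distance transform.** The transform is the separable lower-envelope
algorithm with per-axis physical weights, exact to machine precision (the
test suite asserts agreement with an $O(n^2)$ brute force within $10^{-9}$
mm, anisotropic spacings included). A chamfer approximation would risk
flipping seed membership where $s\,d$ is compared against physical
distances.

**Morphology through the distance transform.** Dilation by the discrete
Euclidean ball is the sublevel set $\{d(\cdot, B) \le r\}$ and erosion its
dual on the background-padded complement, which equals the literal Minkowski
operations with the ball offset set (exhaustively checked against a shift
oracle). Closing is computed on a padded lattice and cropped: since the
closing of a set is contained in the closing of its bounding box, the crop
is lossless, closing is extensive and idempotent, and a full mask closes to
itself, while the image border still never acts as bone. Comparisons use
squared distances with a $10^{-9}$ slack so that offsets lying exactly on
the ball boundary are included deterministically.

**Watershed determinism.** The flood claims a voxel the moment a labeled
neighbor enqueues it; the queue pops by decreasing distance with
first-in-first-out tie-breaking and is initialized in lexicographic voxel
order. Output is therefore bit-reproducible, and a scan-based
reimplementation (no heap) reproduces it voxel-for-voxel on randomized
instances with deliberate ties. Background components unreachable from any
seed (possible only in degenerate inputs, e.g. unfilled enclosed voids) are
assigned "other", or the single present class when only one class was
seeded; no voxel is left as a watershed line. Tie-break at the exact
distance minimum between two fronts goes to whichever front's cascade
enqueued the voxel first.

**A confinement property of this watershed.** Because the flood front of a
seed set reaches any voxel $u$ at "phase" equal to the minimum distance
value along the best path from the seeds, and the exterior distance field
increases monotonically away from the bone, the border-seeded "other" front
reaches every exterior voxel at phase $d(u)$ — never later than the endocast
front, whose paths must pass a crack or canal saddle. The endocast label
therefore cannot escape past the outer surface through any gap narrower
than the exterior's own features; what unfilled cracks actually cost is
*internal*: the endocast region grows thin fins into the crack planes
(dozens to hundreds of voxels beyond the anatomical cavity on the cracked
test phantom), and enclosed diploic voids survive as spurious background.
Void filling removes both, which is exactly what the cracked-shell test
demonstrates: with $r = 6$ the segmented endocast stays entirely inside the
cavity; with $r = 0$ it escapes into the crack.

**Polygonization by marching tetrahedra.** Each lattice cell is split into
the six Freudenthal tetrahedra sharing the main diagonal. This decomposition
is face-consistent between neighbouring cells and a tetrahedron has no
ambiguous sign configuration, so the extracted isosurface is closed and
two-manifold *by construction* rather than by case-table bookkeeping — the
structural guarantee the whole pipeline exists to provide. (A 15-case
marching-cubes table with a consistent ambiguity resolution would also
serve; the tetrahedral route makes the guarantee inspectable.) Surface
vertices are keyed by the global lattice edge they lie on, so adjacent cells
share vertices exactly and watertightness is combinatorial; interpolation
parameters are clamped to $[10^{-6}, 1-10^{-6}]$ so no triangle degenerates
when a corner value hits the isovalue exactly. Triangles are oriented so
normals point from the enclosed air into the solid, making the
divergence-theorem volume of the endocast positive. The cost relative to
marching cubes is roughly twice the triangle count, which downstream
simplification (out of scope here) removes.

**Masking and the fill value.** Cells are polygonized iff at least one of
their eight corners is an endocast voxel. Inside the polygonizer every
non-endocast voxel reads as $\max(\text{value}, t + \varepsilon)$ with
$\varepsilon$ one quantization step (+1 for integer CT numbers): every
air-valued voxel of the field is then an endocast voxel, so every
surface-crossing cell is in the mask and the surface closes. This clamp also
covers a subtle case `mask_fill()` alone does not: bone voxels that noise
pushed below $t$ are background at binarization, refilled by closing, and
hence unlabeled with air-like stored values; without the clamp they could
open the surface in cells with no endocast corner. If an endocast voxel lies
on the domain border (possible only in $\hat t$ mode), the lattice is padded
by one solid voxel so the guarantee is unconditional. Filling with exactly
$t$ (the natural first reading) would make the isocontour degenerate at
filled voxels; $\varepsilon$ preserves the intent at no perceptible surface
displacement.

**Validation.** `validate_mesh()` performs exact combinatorial checks (every
undirected edge in exactly two faces; no directed edge repeated; Euler
characteristic $V - E + F$) plus signed volume and area. Every mesh the
pipeline produces is asserted watertight before it is returned; a failure is
an internal error, not a warning.

## The phantom generator

`generate_phantom()` builds the geometry the method must handle, with exact
analytic ground truth: a spherical bone shell (or a solid ball with a
toroidal cavity, the genus-1 test case) containing a cavity, with optional
cylindrical canal openings (foramen magnum analogue), small spherical voids
placed in the shell wall (diploic space), thin planar cracks (≤ 1 voxel),
and additive Gaussian noise. Membership is decided at voxel centres with no
partial-volume averaging, so the truth mask and the analytic cavity volume
($\tfrac43\pi r^3$, $2\pi^2 R r^2$) are exact; noise is the only blur
source. A single seed drives void placement and noise, and generation is
bit-reproducible. `generate_two_cavity_phantom()` adds the failure mode the
alternative seeding exists for: a large breached space next to a smaller
enclosed target cavity.

Defaults are one realistic setting, chosen once: 64³ voxels at 1 mm
(clinical cranial CT is ~0.5 mm over 512² slices; the phantom keeps the same
geometry an order of magnitude smaller so the full suite runs in seconds),
bone 400 / air −1000 on the Hounsfield-like scale, noise sd 50 where noise
is wanted (the air–bone gap of 1400 is then 28 sd, so binarization is
essentially deterministic, as it is for real bone windows), shell radius
13–16 mm with 3–6 mm walls, canal radius 8 mm (wide enough that the r = 6
closing must *not* seal it), crack thickness 1 voxel. Geometric consistency
rules are enforced rather than assumed: voids need wall thickness
$> 2 \cdot \text{radius} + 2$ voxels of clearance; a torus tube must be
wider than the closing ball (a cavity that cannot contain the structuring
element is, by definition of closing, filled whole) and deeper than the
residual exterior distance maximum, or it stops being "the largest empty
space" and the automatic mode's core assumption fails by construction —
with defaults, major 9 / tube 7 mm inside a 17 mm ball.

What the phantom does **not** emulate: partial-volume ramps at bone-air
interfaces, beam hardening, ring artefacts, the thin-bone attenuation loss
that makes real isovalue choice delicate, and anatomical shape. Passing
tests therefore demonstrate the algorithmic properties (closedness,
determinism, seed safety, oracle exactness, isovalue robustness of the
*geometry*) — not that any particular isovalue is right for a given scanner
or specimen.

## What the test suite establishes

At the problem sizes above (48³–72³ phantoms; ≤ 12³ randomized oracle
instances, 100 per kernel), the suite asserts: every pipeline mesh across
ten phantom configurations — enclosed, 1–3 openings, torus, cracked, noisy,
anisotropic — is watertight, edge-manifold and orientation-consistent; the
enclosed 10 mm cavity is recovered at Dice ≥ 0.98 with mesh volume within 5%
of the analytic 4188.8 mm³; the distance transform matches brute force to
10⁻⁹ mm and the watershed matches its scan-based oracle exactly; meshes
extracted at isovalues 25/50/75% across the air–bone gap differ by a mean
surface distance below one voxel pitch; void filling confines the
segmentation on a cracked shell while its absence lets it escape; the
distance-threshold mode recovers a cavity the automatic mode provably
misses; and repeated extraction is byte-identical. `scripts/acceptance.R`
recomputes all of these quantities from scratch.

## Known limitations

* The closing that fills voids also rounds voxel-scale concavities of the
  *cavity* wall inward; on a discrete 10 mm sphere this costs ~1.3% of the
  enclosed volume and is the main contributor to Dice ≈ 0.983 rather than
  1.0. It is inherent to the method (the segmentation runs on the filled
  mask), not to this implementation.
* Openings are sealed by flat caps at the label boundary, which sits at the
  watershed saddle; where exactly a foramen is "closed" is a modelling
  convention, not an anatomical fact, and differs between operators and
  methods alike.
* The DICOM reader covers uncompressed little-endian single-frame CT series
  only (no undefined-length sequences, no compressed transfer syntaxes);
  NIfTI/NRRD are the robust interchange paths.
* No mesh simplification or smoothing: the marching-tetrahedra output is
  dense by design and meant for downstream processing.
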