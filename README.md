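# endocast

Automatic extraction of endocranial surfaces from CT volumes of crania.

In virtual anthropology the endocast — the cast of the braincase interior —
stands in for the brain that did not fossilize. Getting it out of a CT scan
by hand means separating the endocranial isosurface from the exocranial one
millimetres away, slice by slice; this package automates the whole
procedure and guarantees a closed two-manifold result, so the mesh is
immediately usable for volume estimation, registration, morphometrics or
3D printing.

## Method

Given a CT volume $V$ and an isovalue $t$, the pipeline runs three stages:

1. **Binarize & fill voids.** Bone mask $B = \{V \ge t\}$, then
   $B \leftarrow B \cup \mathrm{blackhat}_r(B) = \mathrm{closing}_r(B)$ with
   a ball structuring element of radius $r$ (default 6 voxels): diploic
   voids and cracks narrower than the ball become bone, so they cannot
   masquerade as empty space.
2. **Segment by watershed on the distance field.** With $d(\cdot)$ the
   exact Euclidean distance (mm) to the nearest bone voxel, every background
   border voxel $b$ seeds the "other" region together with its ball of
   radius $s\,d(b)$ ($s = 0.9 < 1$, so seed balls can never cross bone); the
   remaining maximum of $d$ — necessarily the cavity centre, the largest
   enclosed empty space — seeds the endocast. Priority flooding by
   decreasing $d$ over the 26-neighborhood partitions all background; the
   boundary settles across the distance saddles of the foramina. For
   specimens whose endocast is *not* the largest space, an alternative mode
   thresholds the distance field at $\hat t$ (mm) and takes the largest
   interior connected component instead.
3. **Masked polygonization.** "Other" voxels are filled just above $t$;
   marching tetrahedra restricted to cells touching the endocast region
   extracts the isosurface at $t$ — closed and two-manifold by
   construction, sealed flat across the openings, vertices in physical mm.

Only $t$ and $r$ require judgement; everything else is defaulted. A
synthetic cranium-phantom generator (bone shell, cavity, diploic voids,
cracks, canal openings, noise, exact analytic ground truth) makes the whole
pipeline testable without any CT data.

## Worked example

```r
library(endocast)

# a cranium phantom: 13 mm bone shell, 10 mm cavity, an 8 mm basal canal
# (foramen magnum analogue), CT noise sd 50
spec <- phantom_spec(outer_radius = 13, thickness = 3, noise_sd = 50,
                     openings = list(list(direction = c(0, 0, -1), radius = 8)))
ph <- generate_phantom(spec)

res <- run_pipeline(pipeline_config(ph$grid, threshold_t = -300))
res
#> <endocast_extraction>
#> <tri_mesh> 5626 vertices, 11248 faces
#> <mesh_report> watertight: TRUE, edge-manifold: TRUE, oriented: TRUE
#>   Euler characteristic 2, 1 component(s)
#>   signed volume 4248.33 mm^3, area 1572.25 mm^2
#>           stage seconds                            detail
#>            read   0.000                   64x64x64 voxels
#>        binarize   0.035                   4360 foreground
#>   fill_cavities   0.046     4488 foreground (+128 filled)
#>  distance_field   0.014                      max 41.57 mm
#>         seeding   0.762 247832 other, 2373 endocast seeds
#>       watershed   0.113       253558 other, 4098 endocast
#>       mask_fill   0.015               fill value -299.998
#>      polygonize   0.060        5626 vertices, 11248 faces

dice_coefficient(res$labels$values == LABELS[["endocast"]],
                 ph$truth$cavity_mask)
#> [1] 0.9634703
ph$truth$analytic_volume
#> [1] 4188.79
```

Reading the output: the mesh is watertight, edge-manifold and consistently
oriented with Euler characteristic 2 — a single closed genus-0 surface. Its
signed volume (4248 mm³) slightly exceeds the analytic cavity volume
(4189 mm³) because the segmentation legitimately follows the open canal
down to its watershed saddle before the cap seals it; on the same phantom
without the canal the volume error is ~1.3% and the Dice overlap with
ground truth 0.983. `write_mesh(res$mesh, "endocast.ply")` exports PLY
(binary little-endian; STL and OBJ also supported), and `read_volume()`
ingests DICOM series directories, NIfTI-1, NRRD and raw+JSON-sidecar
volumes.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/endocast.R phantom --spec inst/extdata/phantom_default.yaml --out /tmp/ph
Rscript inst/cli/endocast.R extract --input /tmp/ph_volume.nii.gz --threshold -300 --output /tmp/endo.ply
Rscript inst/cli/endocast.R meshcheck --mesh /tmp/endo.ply
```

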