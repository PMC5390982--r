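# Stage 3: fill the "other" space and polygonize only the endocast region.

# One representable quantization step above the isovalue: +1 for
# integer-valued CT volumes, a relative epsilon otherwise.  Filling with
# exactly t would make the isocontour degenerate at filled voxels; one step
# above keeps them solid without moving the surface perceptibly.
quant_step <- function(values) {
  rng <- range(values)
  if (all(values == round(values))) 1 else max((rng[2] - rng[1]) * 1e-6, 1e-9)
}

#' Fill "other"-labeled voxels so openings become sealed
#'
#' Replaces the value of every "other" voxel by the binarization isovalue
#' plus one quantization step, so that after filling the endocast air region
#' is completely surrounded by values at or above the isovalue: natural
#' openings (foramen magnum, canals) read as solid and the isosurface closes
#' across them.  Endocast and foreground voxels keep their original CT
#' values, preserving sub-voxel surface detail.
#'
#' @param grid The original [voxel_grid()].
#' @param labels [label_volume()] from [marker_watershed()] on the same
#'   lattice.
#' @param t The binarization isovalue.
#' @return A [voxel_grid()] with the "other" space filled.
#' @export
mask_fill <- function(grid, labels, t) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(labels, "label_volume"))
  stopifnot_same_lattice(grid, labels, "mask_fill")
  v <- grid$values
  v[labels$values == LABELS[["other"]]] <- t + quant_step(grid$values)
  voxel_grid(v, grid$spacing, grid$origin)
}

#' Polygonize the endocast region of a masked volume
#'
#' Isosurface extraction at isovalue `t` with linear edge interpolation,
#' restricted to lattice cells having at least one endocast corner voxel.
#' Cells are polygonized by marching tetrahedra over the Freudenthal six-tet
#' decomposition, which is face-consistent across neighbouring cells and free
#' of ambiguous configurations.  During extraction every non-endocast voxel
#' reads as at least one quantization step above `t`, so the only air region
#' is the endocast itself and the extracted surface is a closed two-manifold;
#' this is asserted on the output and a failure raises an internal
#' consistency error.  If an endocast voxel happens to lie on the domain
#' border, the lattice is padded by one solid voxel first so the guarantee
#' still holds.
#'
#' @param filled [voxel_grid()] from [mask_fill()].
#' @param labels [label_volume()] from [marker_watershed()], containing at
#'   least one endocast voxel.
#' @param t Isovalue (same as used for binarization).
#' @return A [tri_mesh()] in physical mm with `meta$isovalue`,
#'   `meta$ncells` (number of polygonized cells) and `meta$report` (the
#'   [validate_mesh()] report).  Normals point from the enclosed air into the
#'   surrounding solid, so the report's signed volume is the positive
#'   endocast volume.
#' @export
masked_marching_cubes <- function(filled, labels, t) {
  stopifnot(inherits(filled, "voxel_grid"), inherits(labels, "label_volume"))
  stopifnot_same_lattice(filled, labels, "masked_marching_cubes")
  lv <- labels$values
  if (!any(lv == LABELS[["endocast"]]))
    stop("no endocast voxels to polygonize", call. = FALSE)
  vals <- filled$values
  origin <- filled$origin
  dims <- dim(vals)
  fill <- t + quant_step(vals)

  endo <- lv == LABELS[["endocast"]]
  on_border <- any(endo[c(1L, dims[1]), , ]) || any(endo[, c(1L, dims[2]), ]) ||
    any(endo[, , c(1L, dims[3])])
  if (on_border) {
    m <- c(1L, 1L, 1L)
    vals <- pad_array(vals, m, value = fill)
    lv <- pad_array(lv, m, value = LABELS[["other"]])
    origin <- origin - filled$spacing
    dims <- dim(vals)
  }

  res <- march_tets_cpp(as.double(vals), as.integer(lv), dims,
                        filled$spacing, origin, t, fill)
  mesh <- tri_mesh(res$vertices, res$faces,
                   meta = list(isovalue = t, ncells = res$ncells))
  report <- validate_mesh(mesh)
  if (!report$watertight || !report$edge_manifold)
    stop("internal consistency error: masked polygonization produced a ",
         "non-watertight surface (masking bug)", call. = FALSE)
  mesh$meta$report <- report
  mesh
}
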