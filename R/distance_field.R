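# Stage 2a: exact Euclidean distance field of the filled bone mask.

#' Exact Euclidean distance transform
#'
#' For every voxel, the exact minimum physical distance (mm) from its centre
#' to the centre of the nearest foreground voxel, respecting anisotropic
#' spacing.  Foreground voxels get exactly zero.  The transform is exact (a
#' separable lower-envelope algorithm, not a chamfer approximation): the
#' watershed seeding radii `s * d` and the distance threshold are compared
#' against these values in mm, and approximation error could flip seed
#' membership.
#'
#' @param bin A [binary_volume()] with at least one foreground voxel.
#' @return A [distance_volume()] on the same lattice.
#' @export
euclidean_distance_transform <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$values))
    stop("distance transform undefined: volume has no foreground voxel",
         call. = FALSE)
  d2 <- edt_sq_cpp(as.logical(bin$values), dim(bin$values), bin$spacing)
  distance_volume(array(sqrt(d2), dim(bin$values)), bin$spacing, bin$origin)
}
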