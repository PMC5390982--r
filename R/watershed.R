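# Stage 2c: marker-controlled watershed on the distance field.

#' Expand seed labels over the background by watershed
#'
#' Priority flooding of the (inverted) distance field: starting from the seed
#' voxels, the unlabeled background voxel fronts advance in order of
#' decreasing distance value over the 26-neighborhood, each voxel taking the
#' label of the already-labeled neighbor that enqueued it first.  Ties in
#' distance break first-in-first-out, and the queue is seeded in
#' lexicographic voxel order, so the segmentation is bit-reproducible.
#' Region boundaries settle along distance ridges/saddles -- i.e. across the
#' narrow openings (foramina) that connect the endocranial space to the
#' exterior.
#'
#' Every background voxel ends up labeled ("no watershed line"): background
#' components unreachable from any seed are assigned "other" (or the single
#' seeded class when only one class is present).
#'
#' @param dist A [distance_volume()] (zero exactly on bone, which identifies
#'   the foreground).
#' @param seeds A [label_volume()] with at least one seed voxel.
#' @return A [label_volume()] in which every background voxel is "other" or
#'   "endocast" and every foreground voxel is unlabeled.
#' @export
marker_watershed <- function(dist, seeds) {
  stopifnot(inherits(dist, "distance_volume"), inherits(seeds, "label_volume"))
  stopifnot_same_lattice(dist, seeds, "marker_watershed")
  fg <- dist$values == 0
  sv <- seeds$values
  if (any(sv != LABELS[["unlabeled"]] & fg))
    stop("seeds assigned to foreground voxels", call. = FALSE)
  n_other <- sum(sv == LABELS[["other"]])
  n_endo <- sum(sv == LABELS[["endocast"]])
  if (n_other + n_endo == 0L)
    stop("marker_watershed: seed volume contains no seeds", call. = FALSE)
  fallback <- if (n_other > 0L) LABELS[["other"]] else LABELS[["endocast"]]
  lab <- watershed_cpp(as.double(dist$values), as.integer(sv),
                       as.logical(fg), dim(sv), as.integer(fallback))
  label_volume(array(lab, dim(sv)), seeds$spacing, seeds$origin)
}
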