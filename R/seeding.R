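# Stage 2b: automatic watershed seed assignment.
#
# The endocranial cavity is (normally) the largest empty space enclosed by
# bone, so its centre carries the largest distance value once the exterior is
# excluded.  Border voxels seed the "other" region together with balls of
# radius s*d(b) (s < 1, so the balls can never cross bone); the remaining
# global distance maximum seeds the endocast.  For crania whose endocast is
# not the largest space, the alternative thresholds the distance field at
# t-hat and takes the border-touching components as "other" and the largest
# interior component as "endocast".

#' Seeding parameters
#'
#' @param s Scaling factor in (0, 1) applied to the distance value when
#'   stamping seed balls (`s = 0` degenerates to border voxels only).  Larger
#'   values blanket more of the exterior so the residual distance maximum
#'   falls inside the cranium; 0.9 is the package default.
#' @param t_hat Optional distance threshold in mm; when given, the
#'   alternative distance-threshold seeding mode is selected.  The guideline
#'   is to pick it large enough to pin off all bottlenecks (foramina)
#'   connecting to the endocranial space, e.g. 10-15 mm for small primate
#'   crania.
#' @return Object of class `seed_params`.
#' @export
seed_params <- function(s = 0.9, t_hat = NULL) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s < 1)
  if (!is.null(t_hat))
    stopifnot(is.numeric(t_hat), length(t_hat) == 1L, t_hat > 0)
  structure(list(s = as.double(s), t_hat = t_hat), class = "seed_params")
}

#' Seed the "other" region from the image border
#'
#' Assigns the "other" label to every background voxel on a face, edge or
#' corner of the image domain, and to every background voxel within physical
#' distance `s * d(b)` of some border voxel `b`.  Because `s < 1` and `d(b)`
#' is the distance to the nearest bone, no stamped ball can contain a
#' foreground voxel: seeding is always safe.
#'
#' @param dist [distance_volume()] computed from `bin`.
#' @param bin The [binary_volume()] the distances were computed from.
#' @param s Scaling factor, `0 <= s < 1`.
#' @return A [label_volume()]; if the border contains no background voxel the
#'   result is all-unlabeled, carries attribute `no_border_seeds = TRUE` and
#'   a warning is issued.
#' @export
border_seeds <- function(dist, bin, s = 0.9) {
  stopifnot(inherits(dist, "distance_volume"), inherits(bin, "binary_volume"))
  stopifnot_same_lattice(dist, bin, "border_seeds")
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s < 1)
  stamped <- stamp_border_cpp(as.double(dist$values), as.logical(bin$values),
                              dim(bin$values), bin$spacing, s)
  lab <- array(ifelse(stamped, LABELS[["other"]], LABELS[["unlabeled"]]),
               dim(bin$values))
  out <- label_volume(lab, bin$spacing, bin$origin)
  if (!any(stamped)) {
    warning("no background voxels on the image border: no 'other' seeds assigned")
    attr(out, "no_border_seeds") <- TRUE
  }
  out
}

#' Seed the endocast at the residual distance maximum
#'
#' Among the still-unlabeled background voxels, the one with the greatest
#' distance value must be the centre of the endocranial cavity (the exterior
#' maxima having been blanketed by [border_seeds()]).  That voxel `e` and
#' every unlabeled background voxel within physical radius `s * d(e)` of it
#' receive the "endocast" label.  Ties for the maximum break to the lowest
#' linear (x-fastest) index, so the result is deterministic.
#'
#' @param dist A [distance_volume()] (zero exactly on bone).
#' @param labels [label_volume()] from [border_seeds()].
#' @param s Scaling factor, `0 <= s < 1`.
#' @return The updated [label_volume()] with at least one endocast voxel.
#' @export
endocast_seed <- function(dist, labels, s = 0.9) {
  stopifnot(inherits(dist, "distance_volume"), inherits(labels, "label_volume"))
  stopifnot_same_lattice(dist, labels, "endocast_seed")
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s < 1)
  d <- dist$values
  cand <- d > 0 & labels$values == LABELS[["unlabeled"]]
  if (!any(cand))
    stop("endocast seeding failed: no unlabeled background voxel remains; ",
         "consider the distance-threshold seeding mode (t_hat)", call. = FALSE)
  dm <- d
  dm[!cand] <- -Inf
  e <- which.max(dm) # first (lowest-index) maximum
  ed <- d[e]
  idx <- arrayInd(e, dim(d))
  R <- s * ed
  lab <- labels$values
  # stamp the endocast ball over the unlabeled background near e
  dims <- dim(d)
  rr <- pmin(pmax(floor(R / dist$spacing), 0), dims - 1L)
  sl <- lapply(1:3, function(a)
    max(1L, idx[a] - rr[a]):min(dims[a], idx[a] + rr[a]))
  sub <- as.matrix(expand.grid(i = sl[[1]], j = sl[[2]], k = sl[[3]]))
  dd2 <- ((sub[, 1] - idx[1]) * dist$spacing[1])^2 +
    ((sub[, 2] - idx[2]) * dist$spacing[2])^2 +
    ((sub[, 3] - idx[3]) * dist$spacing[3])^2
  lin <- sub[, 1] + dims[1] * (sub[, 2] - 1L) + dims[1] * dims[2] * (sub[, 3] - 1L)
  take <- dd2 <= R^2 & cand[lin]
  lab[lin[take]] <- LABELS[["endocast"]]
  lab[e] <- LABELS[["endocast"]]
  out <- label_volume(lab, labels$spacing, labels$origin)
  attr(out, "endocast_centre") <- as.integer(idx)
  attr(out, "endocast_centre_distance") <- ed
  out
}

#' Distance-threshold seeding (alternative mode)
#'
#' For crania whose endocast is not the largest empty space (e.g. small
#' primate crania, broken specimens), seeds are obtained by binarizing the
#' distance field at `t_hat`: among the 26-connected components of
#' `{background, d >= t_hat}`, those touching the image border become "other"
#' (merged) and the largest interior component becomes "endocast".  `t_hat`
#' should exceed the distance radius of every bottleneck (foramen) connecting
#' to the endocranial space so that the endocast component separates from the
#' exterior.
#'
#' @param dist [distance_volume()] computed from `bin`.
#' @param bin The source [binary_volume()].
#' @param t_hat Distance threshold in mm, > 0.
#' @return A [label_volume()] with both label classes nonempty.  Additional
#'   interior components beyond the largest are left unlabeled and reported
#'   in a warning and in attribute `extra_components` (their voxel counts).
#' @export
threshold_seeds <- function(dist, bin, t_hat) {
  stopifnot(inherits(dist, "distance_volume"), inherits(bin, "binary_volume"))
  stopifnot_same_lattice(dist, bin, "threshold_seeds")
  stopifnot(is.numeric(t_hat), length(t_hat) == 1L, t_hat > 0)
  dims <- dim(bin$values)
  S <- !bin$values & dist$values >= t_hat
  if (!any(S))
    stop("threshold seeding failed: no background voxel has distance >= ",
         t_hat, " mm (0 components); lower t_hat", call. = FALSE)
  comp <- array(cc26_cpp(as.logical(S), dims), dims)
  ncomp <- max(comp)
  border_ids <- sort(unique(c(
    comp[c(1L, dims[1]), , ], comp[, c(1L, dims[2]), ], comp[, , c(1L, dims[3])])))
  border_ids <- border_ids[border_ids > 0L]
  interior_ids <- setdiff(seq_len(ncomp), border_ids)
  if (length(border_ids) == 0L)
    stop("threshold seeding failed: none of the ", ncomp, " component(s) of ",
         "{d >= t_hat} touches the image border; adjust t_hat so the exterior ",
         "space survives the threshold", call. = FALSE)
  if (length(interior_ids) == 0L)
    stop("threshold seeding failed: all ", ncomp, " component(s) of ",
         "{d >= t_hat} touch the image border; raise t_hat until it pins off ",
         "the bottlenecks connecting to the endocranial space", call. = FALSE)
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  endo_id <- interior_ids[which.max(sizes[interior_ids])]
  lab <- array(LABELS[["unlabeled"]], dims)
  lab[comp %in% border_ids] <- LABELS[["other"]]
  lab[comp == endo_id] <- LABELS[["endocast"]]
  out <- label_volume(lab, bin$spacing, bin$origin)
  extra <- setdiff(interior_ids, endo_id)
  if (length(extra) > 0L) {
    attr(out, "extra_components") <- sizes[extra]
    warning(length(extra), " additional interior component(s) of {d >= t_hat} ",
            "ignored (voxel counts: ", paste(sizes[extra], collapse = ", "),
            "); the largest was taken as the endocast")
  }
  out
}
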