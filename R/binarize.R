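# Stage 1: isovalue binarization and morphological filling of small bone
# voids (diploic space, cracks).
#
# The morphology primitives use a Euclidean ball structuring element and are
# computed through the exact distance transform: dilation by a ball of radius
# r is the sublevel set {d(., B) <= r}, erosion its dual on the
# background-padded complement.  This is exactly Minkowski dilation/erosion
# with the discrete ball (the set of integer offsets of norm <= r), evaluated
# on the infinite lattice and clipped to the domain, so out-of-bounds voxels
# act as background and never as bone.

#' Binarize a CT volume at an isovalue
#'
#' Classifies voxels into cranium (foreground, value >= `t`) and background.
#' The isovalue is the usual CT bone threshold; for well separated air/bone
#' intensities the mask is insensitive to its exact placement.
#'
#' @param grid A [voxel_grid()].
#' @param t Isovalue threshold (CT number).
#' @return A [binary_volume()] on the same lattice.
#' @export
threshold_binarize <- function(grid, t) {
  stopifnot(inherits(grid, "voxel_grid"), is.numeric(t), length(t) == 1L)
  binary_volume(grid$values >= t, grid$spacing, grid$origin)
}

#' Ball structuring element
#'
#' Radius of the Euclidean ball used by the morphology operators.  With
#' `unit = "voxel"` the ball is isotropic in index space (the conventional
#' choice, default radius 6 voxels for cranial CT); with `unit = "mm"` it is
#' isotropic in physical space, i.e. anisotropic in index space when the
#' voxel spacing is.
#'
#' @param r Nonnegative radius (`r = 0` gives the identity element).
#' @param unit `"voxel"` or `"mm"`.
#' @return Object of class `struct_elem`.
#' @export
struct_elem <- function(r, unit = c("voxel", "mm")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  structure(list(r = as.double(r), unit = unit), class = "struct_elem")
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("<struct_elem> ball, r = %g %s\n", x$r, x$unit))
  invisible(x)
}

#' Integer offsets of a ball structuring element
#'
#' The discrete realization of [struct_elem()]: all integer offsets whose
#' norm (index norm for `unit = "voxel"`, physical norm under `spacing` for
#' `unit = "mm"`) is at most `r`.  Contains the zero offset and is symmetric
#' under negation.
#'
#' @param se A [struct_elem()].
#' @param spacing Voxel spacing, used only for `unit = "mm"`.
#' @return Integer matrix with one offset per row.
#' @export
se_offsets <- function(se, spacing = c(1, 1, 1)) {
  stopifnot(inherits(se, "struct_elem"))
  w <- if (se$unit == "voxel") c(1, 1, 1) else as.double(spacing)
  rng <- lapply(w, function(s) seq.int(-floor(se$r / s), floor(se$r / s)))
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  keep <- (g[, 1] * w[1])^2 + (g[, 2] * w[2])^2 + (g[, 3] * w[3])^2 <=
    se$r^2 + 1e-9
  g2 <- g[keep, , drop = FALSE]
  storage.mode(g2) <- "integer"
  dimnames(g2) <- NULL
  g2
}

# Effective per-axis weights for the SE metric on a given lattice.
se_weights <- function(se, spacing) {
  if (se$unit == "voxel") c(1, 1, 1) else as.double(spacing)
}

# Squared distance to foreground of a plain logical array, in SE metric.
edt_sq_arr <- function(arr, weights) {
  edt_sq_cpp(as.logical(arr), dim(arr), as.double(weights))
}

pad_array <- function(arr, m, value = FALSE) {
  d <- dim(arr)
  out <- array(value, d + 2L * m)
  out[m[1] + seq_len(d[1]), m[2] + seq_len(d[2]), m[3] + seq_len(d[3])] <- arr
  out
}

crop_array <- function(arr, m, d) {
  arr[m[1] + seq_len(d[1]), m[2] + seq_len(d[2]), m[3] + seq_len(d[3])]
}

ball_dilate_arr <- function(arr, r, weights) {
  if (!any(arr)) return(arr)
  d2 <- edt_sq_arr(arr, weights)
  array(d2 <= r^2 + 1e-9, dim(arr))
}

ball_erode_arr <- function(arr, r, weights) {
  m <- as.integer(ceiling(r / weights) + 1L)
  ap <- pad_array(arr, m)
  comp <- !ap
  d2 <- array(edt_sq_arr(comp, weights), dim(ap))
  keep <- ap & (d2 > r^2 + 1e-9)
  crop_array(keep, m, dim(arr))
}

#' Morphological dilation by a ball
#'
#' Minkowski dilation of the foreground with the discrete ball of
#' [struct_elem()]; voxels outside the image domain are background, and the
#' result is clipped to the domain.
#'
#' @param bin A [binary_volume()].
#' @param se A [struct_elem()].
#' @return A [binary_volume()] on the same lattice.
#' @export
dilate <- function(bin, se) {
  stopifnot(inherits(bin, "binary_volume"), inherits(se, "struct_elem"))
  w <- se_weights(se, bin$spacing)
  binary_volume(ball_dilate_arr(bin$values, se$r, w), bin$spacing, bin$origin)
}

#' Morphological erosion by a ball
#'
#' A voxel survives iff the whole ball around it lies in the foreground;
#' out-of-domain voxels count as background, so foreground touching the image
#' border erodes from the border inward.
#'
#' @inheritParams dilate
#' @return A [binary_volume()] on the same lattice.
#' @export
erode <- function(bin, se) {
  stopifnot(inherits(bin, "binary_volume"), inherits(se, "struct_elem"))
  w <- se_weights(se, bin$spacing)
  binary_volume(ball_erode_arr(bin$values, se$r, w), bin$spacing, bin$origin)
}

#' Morphological closing by a ball
#'
#' Dilation followed by erosion, evaluated on the (conceptually infinite)
#' background-padded lattice and clipped to the domain at the end.  Because
#' the closing of a set is contained in the closing of its bounding box, the
#' clip loses nothing: the operator is extensive (`closing(B)` contains `B`)
#' and idempotent, and the full mask closes to itself.
#'
#' @inheritParams dilate
#' @return A [binary_volume()] on the same lattice.
#' @export
closing <- function(bin, se) {
  stopifnot(inherits(bin, "binary_volume"), inherits(se, "struct_elem"))
  w <- se_weights(se, bin$spacing)
  m <- as.integer(ceiling(se$r / w) + 1L)
  ap <- pad_array(bin$values, m)
  cl <- ball_erode_arr(ball_dilate_arr(ap, se$r, w), se$r, w)
  binary_volume(crop_array(cl, m, dim(bin$values)), bin$spacing, bin$origin)
}

#' Fill small cavities in the bone mask
#'
#' Adds to the foreground its black-hat set (closing minus original), which
#' is exactly the morphological closing: background voids narrower than the
#' structuring element -- diploic space, thin cracks -- get bridged and become
#' foreground, while spaces wider than the ball (the endocranial cavity, the
#' exterior) survive.  The result always contains the input.
#'
#' @inheritParams dilate
#' @return A [binary_volume()] with the voids filled.
#' @export
fill_cavities <- function(bin, se) {
  closing(bin, se)
}
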