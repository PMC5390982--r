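# In-memory volume types shared by every pipeline stage.
#
# All volumes live on the same kind of lattice: values[i, j, k] with the x
# index fastest (R's native array order), voxel (i, j, k) centred at
# origin + ((i, j, k) - 1) * spacing in physical millimetres, i.e. 0-based
# offsets from the origin.  Spacing may be anisotropic.

#' Voxel label codes
#'
#' Integer codes used in a [label_volume()]: background voxels are either
#' unlabeled, part of the non-endocranial space ("other"), or part of the
#' endocast.  Foreground (bone) voxels are always unlabeled.
#'
#' @format Named integer vector with entries `unlabeled` (0), `other` (1),
#'   `endocast` (2).
#' @export
LABELS <- c(unlabeled = 0L, other = 1L, endocast = 2L)

new_lattice_volume <- function(values, spacing, origin, class) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = class)
}

#' Construct a scalar CT volume
#'
#' A `voxel_grid` is a 3D scalar field (CT numbers, Hounsfield-like) on an
#' anisotropic lattice.  Voxel `(i, j, k)` (1-based R indices) is centred at
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres; the x index varies
#' fastest.
#'
#' @param values 3D numeric array of finite CT numbers.
#' @param spacing Positive length-3 numeric, mm per voxel along x, y, z.
#' @param origin Length-3 numeric, physical position (mm) of voxel (1,1,1).
#' @return An object of class `voxel_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(0.47, 0.47, 0.5))
#' vox_dims(g)
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("voxel values must all be finite", call. = FALSE)
  new_lattice_volume(values, spacing, origin, "voxel_grid")
}

#' Construct a binary (bone/background) volume
#'
#' @param values 3D logical array; `TRUE` marks foreground (bone).
#' @inheritParams voxel_grid
#' @return Object of class `binary_volume`.
#' @export
binary_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("binary volume must not contain NA", call. = FALSE)
  new_lattice_volume(values, spacing, origin, "binary_volume")
}

#' Construct a distance volume
#'
#' Per-voxel Euclidean distance (mm) to the nearest foreground voxel; zero
#' exactly on the foreground.  Usually produced by
#' [euclidean_distance_transform()].
#'
#' @param values 3D numeric array of nonnegative distances in mm.
#' @inheritParams voxel_grid
#' @return Object of class `distance_volume`.
#' @export
distance_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  new_lattice_volume(values, spacing, origin, "distance_volume")
}

#' Construct a label volume
#'
#' @param values 3D integer array with values from [LABELS].
#' @inheritParams voxel_grid
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "integer"
  if (!all(values %in% LABELS))
    stop("labels must be 0 (unlabeled), 1 (other) or 2 (endocast)",
         call. = FALSE)
  new_lattice_volume(values, spacing, origin, "label_volume")
}

#' Volume dimensions
#' @param x A lattice volume (`voxel_grid`, `binary_volume`, ...).
#' @return Integer triple (nx, ny, nz).
#' @export
vox_dims <- function(x) dim(x$values)

#' Physical volume of one voxel (mm^3)
#' @param x A lattice volume.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# Two volumes share a lattice if dims, spacing and origin agree.
same_lattice <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_lattice <- function(a, b, what) {
  if (!same_lattice(a, b))
    stop(what, ": volumes are not on the same lattice", call. = FALSE)
  invisible(TRUE)
}

# Physical voxel-centre coordinates along each axis.
axis_coords <- function(x) {
  d <- dim(x$values)
  lapply(1:3, function(a) x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %.4g x %.4g x %.4g mm, values in [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_volume> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' @export
print.distance_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<distance_volume> %d x %d x %d, max distance %.3f mm\n",
              d[1], d[2], d[3], max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<label_volume> %d x %d x %d, other %d, endocast %d\n",
              d[1], d[2], d[3], sum(x$values == LABELS[["other"]]),
              sum(x$values == LABELS[["endocast"]])))
  invisible(x)
}
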