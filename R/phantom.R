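# Synthetic cranium phantoms with analytic ground truth.
#
# The phantom emulates every structure the extraction method must handle: a
# high-intensity bone shell enclosing a low-intensity cavity (the endocast
# analogue) inside low-intensity exterior air, with small enclosed voids in
# the shell wall (diploic space), thin planar cracks through the shell, and
# cylindrical canal-like openings (foramen magnum analogue).  Membership is
# decided at voxel centres with no partial-volume antialiasing, so the
# analytic ground truth is exact; Gaussian noise is the only blur source.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

spec_fail <- function(constraint) {
  stop("invalid phantom spec: ", constraint, call. = FALSE)
}

#' Specify a synthetic cranium phantom
#'
#' @param dims Lattice size (voxels), default 64^3.
#' @param spacing Voxel spacing in mm, may be anisotropic.
#' @param center Shell centre in mm (voxel (1,1,1) sits at 0 mm); default the
#'   domain centre.
#' @param outer_radius,thickness Outer radius and wall thickness of the bone
#'   shell in mm; the cavity radius is `outer_radius - thickness`.
#' @param bone_value,air_value CT numbers for bone and air; the gap must be
#'   at least `4 * noise_sd` so a mid-gap isovalue separates the classes.
#' @param shape `"sphere"` (spherical cavity) or `"torus"` (toroidal cavity
#'   of major radius `torus_major`, tube radius `torus_tube`, carved out of a
#'   solid bone ball of radius `outer_radius`; genus-1 test case).
#' @param torus_major,torus_tube Torus radii in mm (used when
#'   `shape = "torus"`).
#' @param openings List of canal-like openings, each
#'   `list(direction = c(..), radius = ..)`: a half-infinite cylinder from
#'   the shell centre along `direction` is carved out of the bone, piercing
#'   the shell on that side (the cavity itself is untouched).
#' @param diploic_voids `list(n = .., radius_range = c(lo, hi))`: `n` small
#'   spherical voids of random radius (mm) placed inside the shell wall,
#'   pairwise separated and disjoint from cavity, exterior, cracks and
#'   openings (rejection sampling; placement failure past a retry cap is an
#'   error).  Only supported for `shape = "sphere"`.
#' @param cracks List of thin planar cracks, each
#'   `list(normal = c(..), thickness = .., offset = ..)`: a slab of the given
#'   thickness (mm, at most one voxel) at signed distance `offset` from the
#'   centre cuts through the shell.
#' @param noise_sd Standard deviation of additive Gaussian noise (CT number).
#' @param seed Integer seed driving void placement and noise; fixed seed
#'   gives bit-identical phantoms.
#' @return Object of class `phantom_spec`.  Validation failures name the
#'   violated constraint.
#' @export
phantom_spec <- function(dims = c(64, 64, 64), spacing = c(1, 1, 1),
                         center = NULL, outer_radius = 16, thickness = 3,
                         bone_value = 400, air_value = -1000,
                         shape = c("sphere", "torus"),
                         torus_major = 9, torus_tube = 7,
                         openings = list(), diploic_voids = list(n = 0),
                         cracks = list(), noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  dims <- as.integer(dims)
  spacing <- as.double(spacing)
  outer_radius <- as.double(outer_radius)
  thickness <- as.double(thickness)
  bone_value <- as.double(bone_value)
  air_value <- as.double(air_value)
  torus_major <- as.double(torus_major)
  torus_tube <- as.double(torus_tube)
  noise_sd <- as.double(noise_sd)
  if (length(dims) != 3L || any(dims < 1L)) spec_fail("dims must be three positive integers")
  if (length(spacing) != 3L || any(spacing <= 0)) spec_fail("spacing must be positive")
  extent <- (dims - 1L) * spacing
  if (is.null(center)) center <- extent / 2
  center <- as.double(center)
  if (outer_radius - thickness <= 0)
    spec_fail("outer_radius - thickness must be positive")
  margin <- 2 * spacing
  if (any(center - outer_radius < margin) ||
        any(center + outer_radius > extent - margin))
    spec_fail("shell must fit inside the domain with >= 2 voxels margin")
  if (bone_value - air_value < 4 * noise_sd)
    spec_fail("bone/air intensity gap must be >= 4 * noise_sd")
  if (shape == "torus") {
    if (torus_tube <= 0 || torus_major <= torus_tube)
      spec_fail("torus radii must satisfy 0 < torus_tube < torus_major")
    if (torus_major + torus_tube > outer_radius - max(spacing))
      spec_fail("torus cavity must fit inside the bone ball")
  }
  dv <- modifyList(list(n = 0L, radius_range = c(1, 2)), diploic_voids)
  dv$n <- as.integer(dv$n)
  if (dv$n < 0L) spec_fail("diploic_voids$n must be nonnegative")
  if (dv$n > 0L && shape != "sphere")
    spec_fail("diploic voids are only supported for the sphere shape")
  if (dv$n > 0L) {
    dv$radius_range <- as.double(dv$radius_range)
    # a void of radius v needs thickness > 2v + 2*margin to sit strictly
    # inside the wall with one voxel of clearance on both sides
    if (thickness <= 2 * dv$radius_range[1] + 2 * max(spacing))
      spec_fail("shell wall too thin for the requested diploic voids")
  }
  for (op in openings) {
    if (is.null(op$direction) || sqrt(sum(op$direction^2)) == 0)
      spec_fail("opening direction must be a nonzero vector")
    if (is.null(op$radius) || op$radius <= 0)
      spec_fail("opening radius must be positive")
  }
  for (cr in cracks) {
    if (is.null(cr$normal) || sqrt(sum(cr$normal^2)) == 0)
      spec_fail("crack normal must be a nonzero vector")
    if (is.null(cr$thickness) || cr$thickness <= 0 ||
          cr$thickness > max(spacing) * 1.001)
      spec_fail("crack thickness must be positive and at most one voxel")
    if (is.null(cr$offset)) cr$offset <- 0
  }
  structure(list(dims = dims, spacing = spacing, center = center,
                 outer_radius = outer_radius, thickness = thickness,
                 bone_value = bone_value, air_value = air_value,
                 shape = shape, torus_major = torus_major,
                 torus_tube = torus_tube, openings = openings,
                 diploic_voids = dv, cracks = cracks,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical coordinate arrays of voxel centres, relative to the shell centre.
phantom_coords <- function(spec) {
  d <- spec$dims
  x <- (seq_len(d[1]) - 1) * spec$spacing[1] - spec$center[1]
  y <- (seq_len(d[2]) - 1) * spec$spacing[2] - spec$center[2]
  z <- (seq_len(d[3]) - 1) * spec$spacing[3] - spec$center[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

normalize3 <- function(v) {
  v <- as.double(v)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic cranium phantom
#'
#' Deterministic for a fixed spec (including its seed).  A voxel is bone iff
#' its centre lies in the shell minus openings, voids and cracks; the ground
#' truth cavity mask is the set of voxel centres inside the cavity, and the
#' analytic cavity volume is the exact continuous volume of that cavity
#' (openings and voids carve the wall only, never the cavity).
#'
#' @param spec A [phantom_spec()].
#' @return List with `grid` (a [voxel_grid()]) and `truth` (class
#'   `phantom_truth`: `cavity_mask` as [binary_volume()], `analytic_volume`
#'   in mm^3, per-structure voxel `counts`, and void placement details).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  R2 <- co$X^2 + co$Y^2 + co$Z^2
  inner <- spec$outer_radius - spec$thickness

  if (spec$shape == "sphere") {
    cavity <- R2 <= inner^2
    bone <- R2 <= spec$outer_radius^2 & !cavity
    analytic <- 4 / 3 * pi * inner^3
  } else {
    rho <- sqrt(co$X^2 + co$Y^2)
    cavity <- (rho - spec$torus_major)^2 + co$Z^2 <= spec$torus_tube^2
    bone <- R2 <= spec$outer_radius^2 & !cavity
    analytic <- 2 * pi^2 * spec$torus_major * spec$torus_tube^2
  }

  n_open <- 0L
  for (op in spec$openings) {
    u <- normalize3(op$direction)
    axial <- co$X * u[1] + co$Y * u[2] + co$Z * u[3]
    rad2 <- pmax(R2 - axial^2, 0)
    cut <- rad2 <= op$radius^2 & axial > 0 & bone
    n_open <- n_open + sum(cut)
    bone[cut] <- FALSE
  }
  n_crack <- 0L
  for (cr in spec$cracks) {
    nh <- normalize3(cr$normal)
    off <- if (is.null(cr$offset)) 0 else cr$offset
    dv <- co$X * nh[1] + co$Y * nh[2] + co$Z * nh[3] - off
    cut <- abs(dv) <= cr$thickness / 2 & bone
    n_crack <- n_crack + sum(cut)
    bone[cut] <- FALSE
  }

  void_centres <- NULL
  void_radii <- NULL
  n_void <- 0L
  values <- NULL
  with_seed(spec$seed, {
    nv <- spec$diploic_voids$n
    if (nv > 0L) {
      rr <- spec$diploic_voids$radius_range
      marg <- max(spec$spacing)
      centres <- matrix(0, 0, 3)
      radii <- numeric(0)
      for (v in seq_len(nv)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          dirv <- normalize3(rnorm(3))
          vr <- runif(1, rr[1], rr[2])
          lo <- inner + vr + marg
          hi <- spec$outer_radius - vr - marg
          if (lo >= hi) next # sampled radius does not fit; retry
          rho <- runif(1, lo, hi)
          vc <- rho * dirv
          ok <- TRUE
          if (nrow(centres) > 0) {
            dd <- sqrt(rowSums(sweep(centres, 2, vc)^2))
            if (any(dd < radii + vr + 2 * marg)) ok <- FALSE
          }
          if (ok) for (cr in spec$cracks) {
            nh <- normalize3(cr$normal)
            off <- if (is.null(cr$offset)) 0 else cr$offset
            if (abs(sum(vc * nh) - off) < vr + cr$thickness / 2 + marg) {
              ok <- FALSE
              break
            }
          }
          if (ok) for (op in spec$openings) {
            u <- normalize3(op$direction)
            axial <- sum(vc * u)
            radial <- sqrt(max(sum(vc^2) - axial^2, 0))
            if (axial > -marg && radial < op$radius + vr + 2 * marg) {
              ok <- FALSE
              break
            }
          }
          if (ok) {
            centres <- rbind(centres, vc)
            radii <- c(radii, vr)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("phantom generation failed: could not place diploic void ", v,
               " after 1000 attempts", call. = FALSE)
      }
      for (v in seq_len(nv)) {
        cut <- (co$X - centres[v, 1])^2 + (co$Y - centres[v, 2])^2 +
          (co$Z - centres[v, 3])^2 <= radii[v]^2 & bone
        n_void <- n_void + sum(cut)
        bone[cut] <- FALSE
      }
      void_centres <- centres
      void_radii <- radii
    }
    vals <- ifelse(bone, spec$bone_value, spec$air_value)
    if (spec$noise_sd > 0)
      vals <- vals + rnorm(length(vals), 0, spec$noise_sd)
    values <- array(vals, spec$dims)
  })

  grid <- voxel_grid(values, spec$spacing)
  truth <- structure(list(
    cavity_mask = binary_volume(cavity, spec$spacing),
    analytic_volume = analytic,
    counts = list(bone = sum(bone), cavity = sum(cavity),
                  void_voxels = n_void, opening_voxels = n_open,
                  crack_voxels = n_crack),
    void_centres = void_centres, void_radii = void_radii,
    bone_mask = binary_volume(bone, spec$spacing)),
    class = "phantom_truth")
  list(grid = grid, truth = truth, spec = spec)
}

#' Two-cavity phantom (endocast not the largest empty space)
#'
#' A solid bone block containing two spherical cavities: a large one (radius
#' 13 mm) breached by a wide channel to the exterior, and a smaller fully
#' enclosed one (radius 10 mm) playing the endocast.  Because the larger
#' space carries the global residual distance maximum, automatic seeding
#' picks the wrong cavity; distance-threshold seeding with a t-hat above the
#' exterior/channel bottleneck separation (e.g. 5 mm here) recovers the
#' enclosed target.  This reproduces the failure mode of small primate or
#' broken crania.
#'
#' @param noise_sd Additive Gaussian noise sd (CT number).
#' @param seed RNG seed for the noise.
#' @return As [generate_phantom()]: list with `grid` and `truth` (truth
#'   describes the enclosed target cavity), plus the geometry in `geometry`.
#' @export
generate_two_cavity_phantom <- function(noise_sd = 0, seed = 1L) {
  dims <- c(72L, 72L, 72L)
  spacing <- c(1, 1, 1)
  d <- dims
  x <- (seq_len(d[1]) - 1) * spacing[1]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(x, each = d[1]), times = d[3]), d)
  Z <- array(rep(x, each = d[1] * d[2]), d)

  box <- X >= 8 & X <= 63 & Y >= 8 & Y <= 63 & Z >= 8 & Z <= 63
  big_c <- c(24, 36, 36)
  big_r <- 13
  tgt_c <- c(50, 36, 36)
  tgt_r <- 10
  big <- (X - big_c[1])^2 + (Y - big_c[2])^2 + (Z - big_c[3])^2 <= big_r^2
  tgt <- (X - tgt_c[1])^2 + (Y - tgt_c[2])^2 + (Z - tgt_c[3])^2 <= tgt_r^2
  channel <- (X - big_c[1])^2 + (Z - big_c[3])^2 <= 7^2 & Y <= big_c[2]
  bone <- box & !big & !tgt & !channel

  values <- NULL
  with_seed(seed, {
    vals <- ifelse(bone, 400, -1000)
    if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
    values <- array(vals, d)
  })
  grid <- voxel_grid(values, spacing)
  truth <- structure(list(
    cavity_mask = binary_volume(tgt, spacing),
    analytic_volume = 4 / 3 * pi * tgt_r^3,
    counts = list(bone = sum(bone), cavity = sum(tgt)),
    bone_mask = binary_volume(bone, spacing)),
    class = "phantom_truth")
  list(grid = grid, truth = truth,
       geometry = list(big_centre = big_c, big_radius = big_r,
                       target_centre = tgt_c, target_radius = tgt_r,
                       channel_radius = 7, suggested_t_hat = 5))
}

#' Read a phantom spec from a YAML or JSON file
#'
#' Field names must match the arguments of [phantom_spec()]; an unknown
#' field is a parse error naming the field.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  fields <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported spec format: .", ext, call. = FALSE))
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(fields), known)
  if (length(bad) > 0L)
    stop("unknown field in phantom spec: '", bad[1], "'", call. = FALSE)
  # yaml reads numeric vectors as lists of scalars in some writers
  for (nm in intersect(names(fields), c("dims", "spacing", "center")))
    fields[[nm]] <- unlist(fields[[nm]])
  do.call(phantom_spec, fields)
}
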