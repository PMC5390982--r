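# End-to-end orchestration: binarize -> fill -> distance field -> seeding ->
# watershed -> mask fill -> masked polygonization -> validation.

#' Configure an extraction run
#'
#' In automatic mode only two parameters matter: the binarization isovalue
#' `threshold_t` (data-dependent, typically picked by inspecting a volume
#' rendering) and the structuring-element radius `se_radius` (the size of the
#' void structures to fill; 6 voxels is a good cranial CT default).
#' Everything else is defaulted.  Setting `distance_threshold_mm` switches to
#' the alternative distance-threshold seeding; configuring both modes at once
#' is an error.
#'
#' @param input Path to a CT volume (any format [read_volume()] accepts) or
#'   an in-memory [voxel_grid()].
#' @param threshold_t Binarization isovalue (CT number).  Required.
#' @param se_radius,se_unit Ball structuring element radius for void filling
#'   (see [struct_elem()]); radius 0 disables filling.
#' @param seed_scale_s Seed ball scaling factor in (0, 1) (see
#'   [border_seeds()]).
#' @param distance_threshold_mm Optional t-hat (mm); presence selects the
#'   alternative seeding mode (see [threshold_seeds()]).
#' @param seeding_mode Optional explicit mode, `"automatic"` or
#'   `"distance_threshold"`; inferred from `distance_threshold_mm` when
#'   omitted.
#' @param output_mesh Optional path for the extracted mesh; a
#'   `<path>.report.json` sidecar with the [validate_mesh()] report is
#'   written next to it.
#' @param mesh_format Mesh format, `"ply"` (binary little-endian, default),
#'   `"stl"` or `"obj"`.
#' @param dump_intermediates If `TRUE`, write the filled bone mask, distance
#'   field and label volume to `dump_dir` as NRRD files.
#' @param dump_dir Directory for intermediate dumps (default: directory of
#'   `output_mesh`).
#' @param connectivity Flood/component connectivity; fixed at 26 and recorded
#'   for reproducibility.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, threshold_t, se_radius = 6,
                            se_unit = c("voxel", "mm"), seed_scale_s = 0.9,
                            distance_threshold_mm = NULL, seeding_mode = NULL,
                            output_mesh = NULL,
                            mesh_format = c("ply", "stl", "obj"),
                            dump_intermediates = FALSE, dump_dir = NULL,
                            connectivity = 26L) {
  se_unit <- match.arg(se_unit)
  mesh_format <- match.arg(mesh_format)
  if (missing(threshold_t) || !is.numeric(threshold_t))
    stop("`threshold_t` (binarization isovalue) is required", call. = FALSE)
  if (connectivity != 26L)
    stop("connectivity is fixed at 26", call. = FALSE)
  if (!is.null(seeding_mode)) {
    seeding_mode <- match.arg(seeding_mode, c("automatic", "distance_threshold"))
    if (seeding_mode == "automatic" && !is.null(distance_threshold_mm))
      stop("both seeding modes configured: seeding_mode = 'automatic' but ",
           "distance_threshold_mm is set", call. = FALSE)
    if (seeding_mode == "distance_threshold" && is.null(distance_threshold_mm))
      stop("seeding_mode = 'distance_threshold' requires distance_threshold_mm",
           call. = FALSE)
  } else {
    seeding_mode <- if (is.null(distance_threshold_mm)) "automatic"
                    else "distance_threshold"
  }
  if (!is.null(distance_threshold_mm))
    stopifnot(is.numeric(distance_threshold_mm), distance_threshold_mm > 0)
  stopifnot(is.numeric(seed_scale_s), seed_scale_s >= 0, seed_scale_s < 1)
  structure(list(input = input, threshold_t = threshold_t,
                 se_radius = se_radius, se_unit = se_unit,
                 seed_scale_s = seed_scale_s,
                 distance_threshold_mm = distance_threshold_mm,
                 seeding_mode = seeding_mode, output_mesh = output_mesh,
                 mesh_format = mesh_format,
                 dump_intermediates = isTRUE(dump_intermediates),
                 dump_dir = dump_dir, connectivity = 26L),
            class = "pipeline_config")
}

#' Run the endocast extraction pipeline
#'
#' Executes binarization, void filling, distance transform, seeding
#' (automatic or distance-threshold), watershed, mask filling and masked
#' polygonization, validates the mesh, and optionally writes the mesh plus a
#' JSON report.  All stages are deterministic: the same input and config
#' produce byte-identical output files.  Any stage error aborts with the
#' stage name; seeding failures carry the actionable message from the
#' seeding functions.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Object of class `endocast_extraction`: `mesh` ([tri_mesh()]),
#'   `report` ([validate_mesh()] report), `labels` (final segmentation),
#'   `seeds`, `binary` (filled bone mask), `distance`, and `log` (one row
#'   per stage with wall time and voxel/triangle counts).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_rows <- list()
  stage <- function(name, detail_fn, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    detail <- detail_fn(res)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = name, seconds = round(el, 3), detail = detail,
      stringsAsFactors = FALSE)
    if (!quiet) message(sprintf("[%s] %.2fs %s", name, el, detail))
    res
  }

  grid <- stage("read", function(g)
    sprintf("%s voxels", paste(dim(g$values), collapse = "x")), {
    if (inherits(config$input, "voxel_grid")) config$input
    else read_volume(config$input)
  })
  se <- struct_elem(config$se_radius, config$se_unit)
  bin <- stage("binarize", function(b) sprintf("%d foreground", sum(b$values)),
               threshold_binarize(grid, config$threshold_t))
  filled <- stage("fill_cavities", function(b)
    sprintf("%d foreground (+%d filled)", sum(b$values),
            sum(b$values) - sum(bin$values)),
    fill_cavities(bin, se))
  dist <- stage("distance_field", function(d)
    sprintf("max %.2f mm", max(d$values)),
    euclidean_distance_transform(filled))
  seeds <- stage("seeding", function(s)
    sprintf("%d other, %d endocast seeds", sum(s$values == LABELS[["other"]]),
            sum(s$values == LABELS[["endocast"]])), {
    if (config$seeding_mode == "automatic") {
      lab <- border_seeds(dist, filled, config$seed_scale_s)
      endocast_seed(dist, lab, config$seed_scale_s)
    } else {
      threshold_seeds(dist, filled, config$distance_threshold_mm)
    }
  })
  labels <- stage("watershed", function(l)
    sprintf("%d other, %d endocast", sum(l$values == LABELS[["other"]]),
            sum(l$values == LABELS[["endocast"]])),
    marker_watershed(dist, seeds))
  fgrid <- stage("mask_fill", function(g) sprintf("fill value %.6g",
                                                  max(g$values[labels$values == LABELS[["other"]]], -Inf)),
                 mask_fill(grid, labels, config$threshold_t))
  mesh <- stage("polygonize", function(m)
    sprintf("%d vertices, %d faces", nrow(m$vertices), nrow(m$faces)),
    masked_marching_cubes(fgrid, labels, config$threshold_t))
  report <- mesh$meta$report

  if (!is.null(config$output_mesh)) {
    write_mesh(mesh, config$output_mesh, config$mesh_format)
    jsonlite::write_json(unclass(report), paste0(config$output_mesh, ".report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (config$dump_intermediates) {
    dd <- config$dump_dir
    if (is.null(dd))
      dd <- if (!is.null(config$output_mesh)) dirname(config$output_mesh) else "."
    dir.create(dd, showWarnings = FALSE, recursive = TRUE)
    write_volume(voxel_grid(filled$values + 0, filled$spacing, filled$origin),
                 file.path(dd, "filled_bone.nrrd"), dtype = "uint8")
    write_volume(voxel_grid(dist$values, dist$spacing, dist$origin),
                 file.path(dd, "distance.nrrd"))
    write_volume(voxel_grid(labels$values + 0, labels$spacing, labels$origin),
                 file.path(dd, "labels.nrrd"), dtype = "uint8")
  }
  structure(list(mesh = mesh, report = report, labels = labels, seeds = seeds,
                 binary = filled, distance = dist,
                 log = do.call(rbind, log_rows), config = config),
            class = "endocast_extraction")
}

#' @export
print.endocast_extraction <- function(x, ...) {
  cat("<endocast_extraction>\n")
  print(x$mesh)
  print(x$report)
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Generate a phantom from a spec file and write it to disk
#'
#' Writes three files next to `out_prefix`: the phantom CT volume
#' (`<prefix>_volume.nii.gz`), the ground-truth cavity mask
#' (`<prefix>_truth_mask.nii.gz`) and a JSON sidecar
#' (`<prefix>_truth.json`) with the analytic cavity volume and per-structure
#' voxel counts.  Deterministic for a fixed spec seed.
#'
#' @param spec A [phantom_spec()] or the path of a YAML/JSON spec file.
#' @param out_prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
make_phantom <- function(spec, out_prefix) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  ph <- generate_phantom(spec)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  p_vol <- paste0(out_prefix, "_volume.nii.gz")
  p_mask <- paste0(out_prefix, "_truth_mask.nii.gz")
  p_json <- paste0(out_prefix, "_truth.json")
  write_volume(ph$grid, p_vol)
  write_volume(voxel_grid(ph$truth$cavity_mask$values + 0,
                          ph$grid$spacing, ph$grid$origin),
               p_mask, dtype = "uint8")
  jsonlite::write_json(list(analytic_volume_mm3 = ph$truth$analytic_volume,
                            counts = ph$truth$counts),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(volume = p_vol, truth_mask = p_mask, truth_json = p_json))
}

#' Dice overlap coefficient between two binary volumes
#'
#' `2|A n B| / (|A| + |B|)`; the standard overlap measure for comparing a
#' segmentation against ground truth.
#'
#' @param a,b [binary_volume()] objects (or logical arrays) on the same
#'   lattice.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  av <- if (inherits(a, "binary_volume")) a$values else a
  bv <- if (inherits(b, "binary_volume")) b$values else b
  stopifnot(identical(dim(av), dim(bv)))
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1)
  2 * sum(av & bv) / denom
}
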