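test_that("the voxelized cavity matches its analytic volume to one surface shell", {
  ph <- generate_phantom(phantom_spec(dims = c(48, 48, 48), outer_radius = 16,
                                      thickness = 3))
  cav <- ph$truth$cavity_mask$values
  expect_equal(ph$truth$analytic_volume, 4 / 3 * pi * 13^3, tolerance = 1e-12)
  # count the cavity surface voxels (6-adjacent to a non-cavity voxel)
  d <- dim(cav)
  interior <- cav
  interior[] <- FALSE
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
    cav[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
    cav[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
    cav[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
    cav[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
    cav[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
    cav[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
    cav[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  n_surface <- sum(cav) - sum(interior)
  expect_lte(abs(sum(cav) - 9202.8), n_surface)
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  sp <- phantom_spec(thickness = 6, noise_sd = 50,
                     diploic_voids = list(n = 5, radius_range = c(1, 2)),
                     seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$truth$cavity_mask$values, b$truth$cavity_mask$values)
  c_ <- generate_phantom(phantom_spec(noise_sd = 50, seed = 43))
  expect_false(identical(a$grid$values, c_$grid$values))
})

test_that("requested diploic voids appear as that many disjoint wall components", {
  sp <- phantom_spec(dims = c(72, 72, 72), outer_radius = 22, thickness = 7,
                     diploic_voids = list(n = 10, radius_range = c(1, 2)),
                     seed = 7)
  ph <- generate_phantom(sp)
  bone <- ph$truth$bone_mask$values
  cav <- ph$truth$cavity_mask$values
  rad <- radius_field(ph$grid)
  voids <- !bone & !cav & rad <= 22
  comp <- r_cc26(voids)
  expect_identical(max(comp), 10L)
  expect_false(any(voids & cav))
})

test_that("invalid phantom specs fail naming the violated constraint", {
  expect_error(phantom_spec(outer_radius = 2, thickness = 3),
               "outer_radius - thickness")
  expect_error(phantom_spec(dims = c(20, 20, 20), outer_radius = 16),
               "margin")
  expect_error(phantom_spec(noise_sd = 1000), "4 \\* noise_sd")
  expect_error(phantom_spec(cracks = list(list(normal = c(0, 0, 1),
                                               thickness = 3))),
               "at most one voxel")
  expect_error(phantom_spec(openings = list(list(direction = c(0, 0, 0),
                                                 radius = 2))),
               "nonzero")
})

test_that("the pipeline recovers ground truth on a default phantom", {
  ph <- generate_phantom(phantom_spec(outer_radius = 13, thickness = 3,
                                      noise_sd = 50, seed = 9))
  res <- run_pipeline(pipeline_config(ph$grid, threshold_t = -300))
  expect_gte(dice_coefficient(endo_mask(res$labels), ph$truth$cavity_mask),
             0.98)
  expect_true(res$report$watertight)
})

test_that("void filling keeps the segmentation inside the cavity when the shell is cracked", {
  ph <- generate_phantom(phantom_spec(outer_radius = 13, thickness = 3,
    cracks = list(list(normal = c(0, 0, 1), thickness = 1, offset = 0))))
  rad <- radius_field(ph$grid)
  res6 <- run_pipeline(pipeline_config(ph$grid, threshold_t = -300,
                                       se_radius = 6))
  endo6 <- endo_mask(res6$labels)
  expect_identical(sum(endo6 & rad > 13), 0L)        # nothing beyond the shell
  expect_identical(sum(endo6 & rad > 10.5), 0L)      # nothing beyond the cavity
  res0 <- run_pipeline(pipeline_config(ph$grid, threshold_t = -300,
                                       se_radius = 0))
  endo0 <- endo_mask(res0$labels)
  expect_gt(sum(endo0 & rad > 10.5), 0)              # escapes into the crack
})

test_that("phantom specs read from YAML and JSON files, rejecting unknown fields", {
  py <- tempfile(fileext = ".yaml")
  writeLines(c("dims: [40, 40, 40]", "outer_radius: 12", "thickness: 3",
               "noise_sd: 25", "seed: 5"), py)
  sp <- read_phantom_spec(py)
  expect_identical(sp$dims, c(40L, 40L, 40L))
  expect_identical(sp$outer_radius, 12)
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(outer_radius = 12, thickness = 3), pj,
                       auto_unbox = TRUE)
  expect_identical(read_phantom_spec(pj)$outer_radius, 12)
  pb <- tempfile(fileext = ".yaml")
  writeLines(c("outer_radius: 12", "shelll_thickness: 3"), pb)
  expect_error(read_phantom_spec(pb), "shelll_thickness")
})
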