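# Shared pipeline pieces for the polygonization tests.
run_stages <- function(grid, t = -300, r = 6, s = 0.9) {
  bin <- fill_cavities(threshold_binarize(grid, t), struct_elem(r))
  d <- euclidean_distance_transform(bin)
  seeds <- endocast_seed(d, border_seeds(d, bin, s), s)
  labels <- marker_watershed(d, seeds)
  list(bin = bin, dist = d, labels = labels,
       filled = mask_fill(grid, labels, t))
}

test_that("mask filling replaces exactly the 'other' voxels", {
  g <- voxel_grid(array(runif(4^3, -1000, 400), c(4, 4, 4)))
  all_endo <- label_volume(array(LABELS[["endocast"]], c(4, 4, 4)))
  expect_identical(mask_fill(g, all_endo, 0)$values, g$values)
  all_other <- label_volume(array(LABELS[["other"]], c(4, 4, 4)))
  out <- mask_fill(g, all_other, 0)$values
  expect_true(all(out == out[1]) && out[1] > 0)
  g2 <- voxel_grid(array(0, c(5, 5, 5)))
  expect_error(mask_fill(g2, all_endo, 0), "lattice")
})

test_that("mask filling seals a canal opening at the isovalue", {
  ph <- generate_phantom(phantom_spec(outer_radius = 13, thickness = 3,
    openings = list(list(direction = c(0, 0, -1), radius = 8))))
  st <- run_stages(ph$grid, t = -300)
  canal_other <- ph$grid$values < -300 & # air in the raw volume
    st$labels$values == LABELS[["other"]]
  expect_gt(sum(canal_other), 0)
  expect_true(all(st$filled$values[canal_other] >= -300))
})

test_that("an enclosed spherical cavity polygonizes to a genus-0 surface with the analytic volume", {
  ph <- generate_phantom(phantom_spec(outer_radius = 13, thickness = 3))
  st <- run_stages(ph$grid)
  mesh <- masked_marching_cubes(st$filled, st$labels, -300)
  rep <- mesh$meta$report
  expect_true(rep$watertight && rep$edge_manifold && rep$orientation_consistent)
  expect_identical(rep$euler_characteristic, 2L)
  expect_identical(rep$connected_components, 1L)
  expect_lt(abs(rep$signed_volume - 4188.79) / 4188.79, 0.05)
  # volume consistency: mesh volume within one cell-shell of the voxel count
  nendo <- sum(endo_mask(st$labels))
  expect_lte(abs(rep$signed_volume - nendo * voxel_volume(ph$grid)),
             mesh$meta$ncells * voxel_volume(ph$grid))
})

test_that("a sealed opening still yields a watertight genus-0 surface", {
  ph <- generate_phantom(phantom_spec(outer_radius = 13, thickness = 3,
    openings = list(list(direction = c(0, 0, -1), radius = 8))))
  st <- run_stages(ph$grid)
  mesh <- masked_marching_cubes(st$filled, st$labels, -300)
  expect_true(mesh$meta$report$watertight)
  expect_identical(mesh$meta$report$euler_characteristic, 2L)
})

test_that("a toroidal cavity yields a watertight genus-1 surface", {
  ph <- generate_phantom(phantom_spec(shape = "torus", outer_radius = 17))
  st <- run_stages(ph$grid)
  mesh <- masked_marching_cubes(st$filled, st$labels, -300)
  expect_true(mesh$meta$report$watertight)
  expect_identical(mesh$meta$report$euler_characteristic, 0L)
})

test_that("polygonization requires endocast voxels and a matching lattice", {
  g <- voxel_grid(array(0, c(4, 4, 4)))
  lab <- label_volume(array(LABELS[["other"]], c(4, 4, 4)))
  expect_error(masked_marching_cubes(g, lab, 0), "no endocast")
  lab2 <- label_volume(array(LABELS[["endocast"]], c(5, 5, 5)))
  expect_error(masked_marching_cubes(g, lab2, 0), "lattice")
})

test_that("mesh validation measures the canonical solids exactly", {
  cube <- tri_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
          c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
          c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
          c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8)))
  rep <- validate_mesh(cube)
  expect_true(rep$watertight && rep$edge_manifold && rep$orientation_consistent)
  expect_identical(rep$euler_characteristic, 2L)
  expect_equal(rep$signed_volume, 1, tolerance = 1e-12)
  expect_equal(rep$area, 6, tolerance = 1e-12)

  open_cube <- tri_mesh(cube$vertices, cube$faces[-(1:2), ])
  rep2 <- validate_mesh(open_cube)
  expect_false(rep2$watertight)

  a <- 2
  tet <- tri_mesh(
    rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
          c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3))),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(3, 1, 4)))
  rep3 <- validate_mesh(tet)
  expect_true(rep3$watertight)
  expect_equal(rep3$signed_volume, a^3 / (6 * sqrt(2)), tolerance = 1e-12)
})

test_that("mesh distances recover analytic offsets between spheres", {
  s10 <- sphere_mesh(10)
  expect_equal(mesh_distance(s10, s10)$mean, 0, tolerance = 1e-12)
  s105 <- sphere_mesh(10.5)
  md <- mesh_distance(s10, s105)
  expect_equal(md$mean, 0.5, tolerance = 0.05)
})

test_that("mesh writers validate and round-trip through every format", {
  cube <- tri_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
          c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
          c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
          c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8)))
  for (fmt in c("ply", "stl", "obj")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_mesh(cube, p)
    m2 <- read_mesh(p)
    expect_identical(nrow(m2$vertices), 8L)
    expect_identical(nrow(m2$faces), 12L)
    expect_equal(validate_mesh(m2)$signed_volume, 1, tolerance = 1e-6)
  }
  empty <- tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_error(write_mesh(empty, tempfile(fileext = ".ply")), "empty")
  expect_error(tri_mesh(matrix(0, 3, 3), rbind(c(1, 2, 5))), "out of range")
  expect_error(tri_mesh(matrix(0, 3, 3), rbind(c(1, 2, 2))), "degenerate")
})
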