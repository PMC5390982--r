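# Standard shell phantom used across the seeding tests: spherical bone shell,
# outer radius 16, thickness 3, centred in a 48^3 unit-spacing grid.
shell48 <- function(...) {
  generate_phantom(phantom_spec(dims = c(48, 48, 48), outer_radius = 16,
                                thickness = 3, ...))
}

test_that("s = 0 seeds exactly the background border voxels", {
  ph <- shell48()
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)
  lab <- border_seeds(d, bin, s = 0)
  dims <- dim(bin$values)
  border <- array(FALSE, dims)
  border[c(1, dims[1]), , ] <- TRUE
  border[, c(1, dims[2]), ] <- TRUE
  border[, , c(1, dims[3])] <- TRUE
  expect_identical(lab$values == LABELS[["other"]], border & !bin$values)
})

test_that("border seed balls never cross bone and never enter the cavity", {
  ph <- shell48()
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)
  rad <- radius_field(bin)
  for (s in c(0.5, 0.7, 0.9)) {
    lab <- border_seeds(d, bin, s = s)
    other <- lab$values == LABELS[["other"]]
    expect_false(any(other & bin$values))          # safety: no bone seeded
    expect_false(any(other & rad < 13))            # nothing inside the cavity
    # the residual maximum (endocast seed) lands strictly inside the cavity
    lab2 <- endocast_seed(d, lab, s = s)
    ctr <- attr(lab2, "endocast_centre")
    expect_lt(rad[ctr[1], ctr[2], ctr[3]], 13)
    endo <- lab2$values == LABELS[["endocast"]]
    expect_true(all(rad[endo] < 13))               # seed ball inside cavity
  }
})

test_that("border stamping equals the literal per-border-voxel definition", {
  ph <- generate_phantom(phantom_spec(dims = c(24, 24, 24), outer_radius = 8,
                                      thickness = 2))
  bin <- threshold_binarize(ph$grid, -300)
  dv <- euclidean_distance_transform(bin)
  s <- 0.9
  lab <- border_seeds(dv, bin, s = s)
  dims <- dim(bin$values)
  # oracle: loop over every border voxel, stamp its ball by scanning all voxels
  co <- arrayInd(seq_len(prod(dims)), dims)
  on_border <- co[, 1] %in% c(1, dims[1]) | co[, 2] %in% c(1, dims[2]) |
    co[, 3] %in% c(1, dims[3])
  want <- array(FALSE, dims)
  for (b in which(on_border & !bin$values)) {
    want[b] <- TRUE
    R2 <- (s * dv$values[b])^2
    dd2 <- (co[, 1] - co[b, 1])^2 + (co[, 2] - co[b, 2])^2 +
      (co[, 3] - co[b, 3])^2
    want[dd2 <= R2 & !bin$values] <- TRUE
  }
  expect_identical(lab$values == LABELS[["other"]], want)
})

test_that("a fully-foreground border yields zero seeds and a warning", {
  m <- array(TRUE, c(8, 8, 8))
  m[3:6, 3:6, 3:6] <- FALSE
  bin <- binary_volume(m)
  d <- euclidean_distance_transform(bin)
  expect_warning(lab <- border_seeds(d, bin, 0.9), "no background voxels")
  expect_true(all(lab$values == LABELS[["unlabeled"]]))
  expect_true(isTRUE(attr(lab, "no_border_seeds")))
})

test_that("the endocast seed picks the larger of two cavities", {
  g <- block_with_cavities(c(64, 48, 48),
                           list(c(20, 24, 24), c(46, 24, 24)), c(10, 5))
  bin <- threshold_binarize(g, -300)
  d <- euclidean_distance_transform(bin)
  lab <- border_seeds(d, bin, 0.9)
  lab2 <- endocast_seed(d, lab, 0.9)
  ctr <- attr(lab2, "endocast_centre")
  expect_lt(sqrt(sum((ctr - 1 - c(20, 24, 24))^2)), 2)
  expect_equal(attr(lab2, "endocast_centre_distance"), 10, tolerance = 0.6)
})

test_that("seeding failure with everything labeled suggests the t-hat mode", {
  ph <- shell48()
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)
  lab <- border_seeds(d, bin, 0)
  full <- lab
  full$values[!bin$values] <- LABELS[["other"]]
  expect_error(endocast_seed(d, full, 0.9), "t_hat")
})

test_that("distance-threshold seeding separates border and interior components", {
  ph <- shell48(openings = list(list(direction = c(0, 0, -1), radius = 4)))
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)
  lab <- threshold_seeds(d, bin, t_hat = 6)
  other <- lab$values == LABELS[["other"]]
  endo <- lab$values == LABELS[["endocast"]]
  expect_gt(sum(other), 0)
  expect_gt(sum(endo), 0)
  rad <- radius_field(bin)
  expect_true(all(rad[endo] < 13))       # endocast component inside the cavity
  expect_true(all(rad[other] > 13))      # border component outside the shell
  # the canal bottleneck (d < t-hat) belongs to neither component
  expect_true(all(d$values[other | endo] >= 6))
  # independent component count on the thresholded set: one border, one interior
  S <- !bin$values & d$values >= 6
  comp <- r_cc26(S)
  expect_identical(max(comp), 2L)
})

test_that("t-hat above the distance maximum is a seeding failure", {
  ph <- shell48()
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)
  expect_error(threshold_seeds(d, bin, t_hat = max(d$values) + 1),
               "no background voxel")
})

test_that("extra interior components are reported and the largest wins", {
  g <- block_with_cavities(c(64, 48, 48),
                           list(c(20, 24, 24), c(46, 24, 24)), c(10, 6))
  bin <- threshold_binarize(g, -300)
  d <- euclidean_distance_transform(bin)
  expect_warning(lab <- threshold_seeds(d, bin, t_hat = 4),
                 "additional interior component")
  endo <- lab$values == LABELS[["endocast"]]
  co <- arrayInd(which(endo), dim(endo))
  # all endocast seeds belong to the radius-10 cavity around (20,24,24)
  expect_true(all((co[, 1] - 21)^2 + (co[, 2] - 25)^2 + (co[, 3] - 25)^2 <= 10.5^2))
  expect_identical(length(attr(lab, "extra_components")), 1L)
})
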