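test_that("distance transform handles degenerate masks analytically", {
  all_fg <- binary_volume(array(TRUE, c(4, 5, 6)))
  expect_true(all(euclidean_distance_transform(all_fg)$values == 0))
  all_bg <- binary_volume(array(FALSE, c(3, 3, 3)))
  expect_error(euclidean_distance_transform(all_bg), "no foreground")
})

test_that("single-voxel source gives exact radial distances", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  d <- euclidean_distance_transform(binary_volume(m))$values
  expect_equal(d[1, 1, 1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(d[5, 5, 5], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(d, brute_edt(m), tolerance = 1e-9)
})

test_that("a foreground plane gives the analytic slab distance under anisotropy", {
  m <- array(FALSE, c(4, 4, 6))
  m[, , 1] <- TRUE
  d <- euclidean_distance_transform(binary_volume(m, spacing = c(1, 1, 2)))$values
  for (k in 1:6) expect_true(all(d[, , k] == 2 * (k - 1)))
})

test_that("the transform matches pairwise brute force on random masks", {
  set.seed(202)
  for (i in 1:25) {
    dms <- sample(3:12, 3, replace = TRUE)
    sp <- sample(c(0.35, 0.47, 0.5, 1, 2), 3, replace = TRUE)
    fg <- array(runif(prod(dms)) < 0.12, dms)
    if (!any(fg)) fg[sample(prod(dms), 1)] <- TRUE
    d <- euclidean_distance_transform(binary_volume(fg, spacing = sp))$values
    expect_lt(max(abs(d - brute_edt(fg, sp))), 1e-9)
    expect_true(all(d[fg] == 0))
  }
})

test_that("the distance field is 1-Lipschitz over all 26-neighbor pairs", {
  ph <- generate_phantom(phantom_spec(dims = c(40, 40, 40), outer_radius = 11,
                                      thickness = 3))
  bin <- threshold_binarize(ph$grid, -300)
  d <- euclidean_distance_transform(bin)$values
  sp <- ph$grid$spacing
  dims <- dim(d)
  for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1),
                 c(1, -1, 0), c(1, 0, -1), c(0, 1, -1),
                 c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))) {
    src <- lapply(1:3, function(a) max(1, 1 - o[a]):min(dims[a], dims[a] - o[a]))
    dst <- lapply(1:3, function(a) src[[a]] + o[a])
    step <- sqrt(sum((o * sp)^2))
    gap <- abs(d[dst[[1]], dst[[2]], dst[[3]]] - d[src[[1]], src[[2]], src[[3]]])
    expect_lte(max(gap), step + 1e-9)
  }
})
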