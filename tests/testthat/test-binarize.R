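test_that("isovalue binarization splits constant and two-valued volumes", {
  g_hi <- voxel_grid(array(500, c(4, 4, 4)))
  expect_true(all(threshold_binarize(g_hi, 0)$values))
  g_lo <- voxel_grid(array(-1000, c(4, 4, 4)))
  expect_false(any(threshold_binarize(g_lo, 0)$values))
  # well-separated air/bone values: any mid-gap isovalue gives the same mask
  set.seed(3)
  two <- voxel_grid(array(sample(c(-1000, 500), 125, replace = TRUE), c(5, 5, 5)))
  m0 <- threshold_binarize(two, -400)$values
  expect_identical(threshold_binarize(two, 0)$values, m0)
  expect_identical(threshold_binarize(two, 400)$values, m0)
})

test_that("ball offsets contain zero and are symmetric under negation", {
  for (se in list(struct_elem(2), struct_elem(3.5, "mm"))) {
    offs <- se_offsets(se, spacing = c(0.5, 1, 2))
    expect_true(any(rowSums(abs(offs)) == 0))
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    expect_identical(key(offs), key(-offs))
  }
})

test_that("closing has its lattice fixed points: empty and full masks", {
  se <- struct_elem(2)
  empty <- binary_volume(array(FALSE, c(7, 7, 7)))
  expect_false(any(closing(empty, se)$values))
  full <- binary_volume(array(TRUE, c(9, 9, 9)))
  expect_true(all(closing(full, se)$values))
})

test_that("closing restores a solid cube with one interior voxel removed", {
  m <- array(TRUE, c(9, 9, 9))
  m[5, 5, 5] <- FALSE
  got <- closing(binary_volume(m), struct_elem(2))$values
  want <- brute_closing(m, ball_offsets(2), 2)
  expect_identical(got, want)
  expect_true(all(got))
})

test_that("cavity filling bridges small voids and spares large ones", {
  # 21^3 solid cube with a 3^3 internal cavity, ball r = 6: cavity filled
  m <- array(FALSE, c(25, 25, 25))
  m[3:23, 3:23, 3:23] <- TRUE
  m[12:14, 12:14, 12:14] <- FALSE
  filled <- fill_cavities(binary_volume(m), struct_elem(6))$values
  expect_true(all(filled[12:14, 12:14, 12:14]))
  expect_identical(filled, brute_closing(m, ball_offsets(6), 6))

  # 41^3 solid cube with a 15^3 cavity, r = 2: too wide to bridge
  m2 <- array(FALSE, c(45, 45, 45))
  m2[3:43, 3:43, 3:43] <- TRUE
  m2[15:29, 15:29, 15:29] <- FALSE
  filled2 <- fill_cavities(binary_volume(m2), struct_elem(2))$values
  expect_false(any(filled2[17:27, 17:27, 17:27]))
  expect_identical(filled2, brute_closing(m2, ball_offsets(2), 2))

  # convex solid block: closing is the identity
  m3 <- array(FALSE, c(15, 15, 15))
  m3[4:12, 3:13, 5:11] <- TRUE
  expect_identical(fill_cavities(binary_volume(m3), struct_elem(3))$values, m3)
})

test_that("dilation and erosion agree exhaustively with the Minkowski oracle", {
  set.seed(101)
  for (i in 1:12) {
    d <- sample(4:12, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.4, d)
    r <- sample(1:3, 1)
    se <- struct_elem(r)
    offs <- ball_offsets(r)
    bv <- binary_volume(m)
    expect_identical(dilate(bv, se)$values, brute_dilate(m, offs))
    expect_identical(erode(bv, se)$values, brute_erode(m, offs))
  }
})

test_that("mm-unit structuring elements respect anisotropic spacing", {
  set.seed(5)
  d <- c(9, 9, 9)
  sp <- c(0.5, 1, 2)
  m <- array(runif(prod(d)) < 0.3, d)
  se <- struct_elem(2, "mm")
  offs <- ball_offsets(2, weights = sp)
  bv <- binary_volume(m, spacing = sp)
  expect_identical(dilate(bv, se)$values, brute_dilate(m, offs))
  expect_identical(erode(bv, se)$values, brute_erode(m, offs))
})

test_that("cavity filling is extensive and closing idempotent on random masks", {
  set.seed(77)
  se <- struct_elem(2)
  for (i in 1:8) {
    m <- array(runif(16^3) < 0.35, c(16, 16, 16))
    bv <- binary_volume(m)
    cl <- closing(bv, se)
    expect_true(all(m <= cl$values))                       # extensive
    expect_identical(closing(cl, se)$values, cl$values)    # idempotent
    expect_identical(fill_cavities(bv, se)$values, cl$values)
  }
})
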