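test_that("volume_cc counts occupied voxels times voxel volume", {
  g1 <- voxel_grid(c(10, 10, 10), c(1, 1, 1))
  expect_equal(volume_cc(structure_mask(array(TRUE, c(10, 10, 10)), g1)), 1.0)
  g2 <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
  expect_equal(volume_cc(structure_mask(array(TRUE, c(10, 10, 10)), g2)), 8.0)
  expect_equal(volume_cc(structure_mask(array(FALSE, c(10, 10, 10)), g1)), 0.0)
  g3 <- voxel_grid(c(10, 10, 10), c(1, 1, 2.5))
  occ <- array(FALSE, c(10, 10, 10)); occ[seq_len(500)] <- TRUE
  expect_equal(volume_cc(structure_mask(occ, g3)), 500 * 2.5 / 1000)
})

test_that("grid and mask invariants are validated", {
  expect_error(voxel_grid(c(0, 5, 5), c(1, 1, 1)), "shape")
  expect_error(voxel_grid(c(5, 5, 5), c(1, -1, 1)), "spacing")
  g <- voxel_grid(c(3, 3, 3), c(1, 1, 1))
  expect_error(structure_mask(array(TRUE, c(2, 2, 2)), g), "dimensions")
  expect_error(dose_grid(array(-1, c(3, 3, 3)), g), "negative")
  expect_error(dose_grid(array(Inf, c(3, 3, 3)), g), "finite")
})

test_that("mask NIfTI round trip preserves occupancy and geometry", {
  g <- voxel_grid(c(12, 10, 8), c(0.9, 1.1, 2.5), origin_mm = c(-4.5, 3.25, 10))
  set.seed(11)
  occ <- array(runif(prod(g$shape)) > 0.6, dim = g$shape)
  m <- structure_mask(occ, g, "blob")
  f <- tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  m2 <- read_mask(f, "blob")
  expect_identical(m2$occupancy, m$occupancy)
  expect_equal(m2$grid$spacing_mm, g$spacing_mm, tolerance = 1e-6)
  expect_equal(m2$grid$origin_mm, g$origin_mm, tolerance = 1e-6)
  expect_identical(m2$grid$shape, g$shape)
  unlink(f)
})

test_that("read_mask binarises at half the maximum value", {
  g <- voxel_grid(c(6, 6, 6), c(1, 1, 1))
  set.seed(3)
  occ <- array(runif(216) > 0.5, dim = c(6, 6, 6))
  f01 <- tempfile(fileext = ".nii.gz")
  f255 <- tempfile(fileext = ".nii.gz")
  write_mask(structure_mask(occ, g), f01)
  img <- RNifti::asNifti(array(255 * occ, dim = c(6, 6, 6)))
  RNifti::writeNifti(img, f255)
  expect_identical(read_mask(f255)$occupancy, read_mask(f01)$occupancy)
  unlink(c(f01, f255))
})

test_that("read_mask rejects non-3D input and warns on all-zero volumes", {
  f2d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), f2d)
  expect_error(read_mask(f2d), "3D")
  fz <- tempfile(fileext = ".nii.gz")
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  write_mask(structure_mask(array(FALSE, c(4, 4, 4)), g), fz)
  expect_warning(mz <- read_mask(fz), "all-zero")
  expect_equal(volume_cc(mz), 0)
  unlink(c(f2d, fz))
})

test_that("dose NIfTI round trip preserves values to float precision", {
  g <- voxel_grid(c(8, 8, 6), c(1, 1, 2.5))
  set.seed(5)
  d <- dose_grid(array(runif(prod(g$shape), 0, 75), dim = g$shape), g)
  f <- tempfile(fileext = ".nii.gz")
  write_dose(d, f)
  d2 <- read_dose(f)
  expect_equal(d2$dose_gy, d$dose_gy, tolerance = 1e-6)
  unlink(f)
})

test_that("resampling is exact for identical grids, constants and linear ramps", {
  g <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
  set.seed(7)
  d <- dose_grid(array(runif(1000, 0, 70), dim = c(10, 10, 10)), g)
  expect_identical(resample_to(d, g)$dose_gy, d$dose_gy)

  # constant field resampled to a strictly interior grid stays constant
  const <- dose_grid(array(70, c(10, 10, 10)), g)
  interior <- voxel_grid(c(7, 7, 7), c(1.7, 1.9, 2.3), origin_mm = c(1, 1, 1))
  expect_equal(resample_to(const, interior)$dose_gy,
               array(70, c(7, 7, 7)), tolerance = 1e-12)

  # trilinear interpolation reproduces a linear ramp exactly at new centres
  x <- (seq_len(10) - 1) * 2
  ramp <- dose_grid(array(rep(5 + 1.5 * x, times = 100), c(10, 10, 10)), g)
  half <- voxel_grid(c(4, 4, 4), c(4, 4, 4), origin_mm = c(1, 1, 1))
  got <- resample_to(ramp, half)$dose_gy
  want_x <- 5 + 1.5 * (1 + (seq_len(4) - 1) * 4)
  expect_equal(got, array(rep(want_x, times = 16), c(4, 4, 4)),
               tolerance = 1e-12)

  far <- voxel_grid(c(4, 4, 4), c(1, 1, 1), origin_mm = c(100, 100, 100))
  expect_error(resample_to(d, far), "disjoint")
})

test_that("expand_margin matches explicit distance enumeration", {
  g <- voxel_grid(c(9, 9, 9), c(1, 1, 2))
  occ <- array(FALSE, c(9, 9, 9)); occ[5, 5, 5] <- TRUE
  m <- structure_mask(occ, g, "pt")
  expect_identical(expand_margin(m, 0)$occupancy, m$occupancy)

  e <- expand_margin(m, 3)
  # oracle: enumerate all voxel-centre distances to the seed voxel
  want <- array(FALSE, c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    want[i, j, k] <- sqrt((i - 5)^2 + (j - 5)^2 + 4 * (k - 5)^2) <= 3
  expect_identical(e$occupancy, want)
  expect_error(expand_margin(m, -1), "nonnegative")
})

test_that("expanding a 10 mm sphere by 3 mm scales volume like (13/10)^3", {
  g <- voxel_grid(c(40, 40, 40), c(1, 1, 1))
  ctr <- c(19.5, 19.5, 19.5)
  x <- (seq_len(40) - 1)
  occ <- outer(outer((x - ctr[1])^2, (x - ctr[2])^2, `+`),
               (x - ctr[3])^2, `+`) <= 100
  m <- structure_mask(occ, g, "sphere")
  e <- expand_margin(m, 3)
  ratio <- volume_cc(e) / volume_cc(m)
  expect_lt(abs(ratio - 2.197) / 2.197, 0.05)
})

test_that("expand_margin volume is nondecreasing in the margin", {
  g <- voxel_grid(c(16, 16, 12), c(1.5, 1, 2.5))
  set.seed(21)
  m <- structure_mask(random_blob(g), g, "blob")
  vols <- vapply(c(0, 0.5, 1, 2, 3.5, 5), function(mm)
    volume_cc(expand_margin(m, mm)), double(1))
  expect_true(all(diff(vols) >= 0))
})
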