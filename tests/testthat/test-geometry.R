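test_that("common grid reproduces its inputs in the identity case", {
  g <- grid_geometry(c(1.5, 1.5, 6), c(10, 10, 4))
  out <- common_grid(g, g, c(1.5, 1.5, 6))
  expect_equal(out$voxel, g$voxel)
  expect_equal(out$dims, g$dims)
  expect_equal(out$origin, g$origin)
})

test_that("the breast protocol grid pair maps to the 1.5 x 1.5 x 6 mm analysis grid", {
  dce <- grid_geometry(c(1.44, 1.44, 2), c(48, 48, 12))
  dw <- grid_geometry(c(1.52, 1.52, 6), c(46, 46, 4))
  out <- common_grid(dce, dw)
  expect_equal(out$voxel, c(1.5, 1.5, 6))
  # grid spans only the shared physical extent
  es <- pmin(breastqmri:::grid_extent(dce)["hi", ],
             breastqmri:::grid_extent(dw)["hi", ])
  eo <- breastqmri:::grid_extent(out)
  expect_true(all(eo["hi", ] <= es + 1e-9))
})

test_that("disjoint extents raise a geometry error", {
  a <- grid_geometry(c(1, 1, 1), c(5, 5, 5), origin = c(0, 0, 0))
  b <- grid_geometry(c(1, 1, 1), c(5, 5, 5), origin = c(100, 0, 0))
  expect_error(common_grid(a, b), "intersection")
})

test_that("trilinear resampling is exact on constant and linear fields", {
  src_grid <- grid_geometry(c(2, 2, 2), c(12, 10, 8))
  w <- breastqmri:::grid_centres(src_grid)

  const <- dynamic_series(array(7, c(src_grid$dims, 2)), src_grid, c(0, 1), "dce")
  tgt <- grid_geometry(c(1.3, 1.7, 2.4), c(8, 6, 4), origin = c(4, 4, 4))
  out <- resample_trilinear(const, tgt)
  expect_equal(as.vector(out$data), rep(7, prod(tgt$dims) * 2))

  # linear ramp along x is reproduced exactly at target coordinates
  ramp <- array(w[, 1], src_grid$dims)
  rs <- resample_trilinear(dynamic_series(ramp, src_grid, 0, "dce"), tgt)
  expect_equal(as.vector(rs$data), breastqmri:::grid_centres(tgt)[, 1], tolerance = 1e-12)
})

test_that("resampling onto the source grid is the identity", {
  g <- grid_geometry(c(1.4, 1.4, 2), c(9, 9, 5))
  set.seed(3)
  arr <- array(rnorm(prod(g$dims) * 3), c(g$dims, 3))
  s <- dynamic_series(arr, g, 1:3, "dwi")
  out <- resample_trilinear(s, g)
  expect_equal(out$data, arr, tolerance = 1e-12)
})

test_that("resampled values respect per-frame source bounds and linearity", {
  set.seed(4)
  g <- grid_geometry(c(1.44, 1.44, 2), c(14, 14, 8))
  tgt <- grid_geometry(c(1.5, 1.5, 6), c(12, 12, 2), origin = c(1.5, 1.5, 4))
  for (rep in 1:5) {
    arr <- array(runif(prod(g$dims) * 2, -5, 5), c(g$dims, 2))
    s <- dynamic_series(arr, g, c(0, 1), "dce")
    out <- resample_trilinear(s, tgt)
    for (f in 1:2) {
      expect_gte(min(out$data[, , , f]), min(arr[, , , f]) - 1e-12)
      expect_lte(max(out$data[, , , f]), max(arr[, , , f]) + 1e-12)
    }
    # commutes with affine maps of the intensities
    s2 <- dynamic_series(3 * arr + 2, g, c(0, 1), "dce")
    out2 <- resample_trilinear(s2, tgt)
    expect_equal(out2$data, 3 * out$data + 2, tolerance = 1e-10)
  }
})

test_that("extrapolation outside the source extent is refused", {
  g <- grid_geometry(c(1, 1, 1), c(5, 5, 5))
  big <- grid_geometry(c(1, 1, 1), c(10, 10, 10))
  s <- dynamic_series(array(0, c(g$dims, 1)), g, 0, "dce")
  expect_error(resample_trilinear(s, big), "extent")
  expect_error(resample_nearest(array(0L, g$dims), g, big), "extent")
})

test_that("nearest-neighbour mask resampling keeps integer labels", {
  g <- grid_geometry(c(1.44, 1.44, 2), c(16, 16, 6))
  mask <- array(0L, g$dims); mask[5:9, 5:9, 2:4] <- 3L
  tgt <- common_grid(g, g, c(1.5, 1.5, 6))
  out <- resample_nearest(mask, g, tgt)
  expect_true(all(out %in% c(0L, 3L)))
  expect_gt(sum(out == 3L), 0)
})
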