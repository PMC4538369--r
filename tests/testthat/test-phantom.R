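test_that("phantom configuration validates its invariants", {
  expect_error(phantom_config(n_timepoints = 1), "2 time points")
  expect_error(phantom_config(dt = 0), "dt")
  expect_error(phantom_config(b_values = c(0, 100, 100)), "increasing")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma")
  expect_error(sample_lesion_parameters(phantom_config(), "cystic"), "unknown class")
})

test_that("zero-variance class distributions are degenerate at the class median", {
  cp <- class_params(
    benign = list(ktrans = c(0.08, 0), kep = c(0.45, 0), vp = c(0.02, 0),
                  f = c(0.06, 0), d_star = c(8e-3, 0), d = c(1.6e-3, 0)),
    malignant = list(ktrans = c(0.35, 0), kep = c(1.3, 0), vp = c(0.06, 0),
                     f = c(0.12, 0), d_star = c(15e-3, 0), d = c(1.0e-3, 0)))
  cfg <- phantom_config(params = cp)
  for (i in 1:5) {
    p <- sample_lesion_parameters(cfg, "benign")
    expect_equal(unname(p$tofts), c(0.08, 0.45, 0.02))
    expect_equal(unname(p$ivim), c(0.06, 8e-3, 1.6e-3))
  }
})

test_that("same seed and config give identical draws and bit-identical volumes", {
  cfg <- small_config(seed = 5, noise_sigma = 0.02)
  set.seed(1); a <- sample_lesion_parameters(cfg, "malignant")
  set.seed(1); b <- sample_lesion_parameters(cfg, "malignant")
  expect_identical(a, b)

  t1 <- build_phantom(cfg); t2 <- build_phantom(cfg)
  expect_identical(t1$lesions, t2$lesions)
  expect_identical(simulate_dce(cfg, t1)$data, simulate_dce(cfg, t2)$data)
  expect_identical(simulate_dw(cfg, t1)$data, simulate_dw(cfg, t2)$data)
})

test_that("empirical class means match configured log-normal moments", {
  cfg <- phantom_config(seed = 2)
  set.seed(77)
  n <- 1e4
  draws <- replicate(n, sample_lesion_parameters(cfg, "malignant")$tofts[["ktrans"]])
  m <- class_param_means(cfg$params, "malignant")[["ktrans"]]
  v <- cfg$params$malignant$ktrans
  sd_theory <- sqrt((exp(v[2]^2) - 1)) * m
  expect_lt(abs(mean(draws) - m), 3 * sd_theory / sqrt(n))

  # configured effect size separates the class means
  ben <- class_param_means(cfg$params, "benign")
  mal <- class_param_means(cfg$params, "malignant")
  expect_true(all(mal[c("ktrans", "kep", "vp", "f", "d_star")] >
                    ben[c("ktrans", "kep", "vp", "f", "d_star")]))
  expect_lt(mal[["d"]], ben[["d"]])
})

test_that("a kinetically inert phantom gives flat DCE frames", {
  cp <- class_params(
    benign = list(ktrans = c(1e-12, 0), kep = c(1e-12, 0), vp = c(1e-12, 0),
                  f = c(0.06, 0), d_star = c(8e-3, 0), d = c(1.6e-3, 0)),
    malignant = list(ktrans = c(1e-12, 0), kep = c(1e-12, 0), vp = c(1e-12, 0),
                     f = c(0.12, 0), d_star = c(15e-3, 0), d = c(1.0e-3, 0)),
    voxel_sdlog = 0)
  cfg <- small_config(noise_sigma = 0, params = cp)
  truth <- build_phantom(cfg)
  dce <- simulate_dce(cfg, truth)
  for (f in 2:dim(dce$data)[4])
    expect_equal(dce$data[, , , f], dce$data[, , , 1], tolerance = 1e-9)
})

test_that("doubling vp doubles the vascular-only concentration curve", {
  t <- seq(0, 8, by = 0.5)
  expect_equal(tofts_forward(t, 0, 1, 0.1), 2 * tofts_forward(t, 0, 1, 0.05))
})

test_that("DW simulation honours the biexponential closed form", {
  cfg <- small_config(noise_sigma = 0)
  truth <- build_phantom(cfg)
  dwi <- simulate_dw(cfg, truth)
  # b = 0 frame equals baseline everywhere
  expect_equal(as.vector(dwi$data[, , , 1]),
               rep(cfg$baseline, prod(cfg$grid_dw$dims)), tolerance = 1e-12)
  v <- which(truth$mask_dw > 0)[1]
  im <- truth$ivim_dw
  expected <- cfg$baseline * (im$f[v] * exp(-cfg$b_values * im$d_star[v]) +
                                (1 - im$f[v]) * exp(-cfg$b_values * im$d[v]))
  flat <- matrix(dwi$data, ncol = length(cfg$b_values))
  expect_equal(flat[v, ], expected, tolerance = 1e-12)
})

test_that("non-physical ground truth is rejected", {
  cfg <- small_config()
  truth <- build_phantom(cfg)
  bad <- truth; bad$tofts_dce$ktrans[1] <- -1
  expect_error(simulate_dce(cfg, bad), "non-physical")
  bad2 <- truth; bad2$ivim_dw$f[1] <- 1.5
  expect_error(simulate_dw(cfg, bad2), "f must lie")
})

test_that("background variance grows monotonically with noise_sigma", {
  vars <- vapply(c(0.01, 0.03, 0.06), function(ns) {
    cfg <- small_config(seed = 13, noise_sigma = ns)
    truth <- build_phantom(cfg)
    dce <- simulate_dce(cfg, truth)
    bg <- which(truth$mask_dce == 0)
    var(as.vector(matrix(dce$data, ncol = dim(dce$data)[4])[bg, 1]))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("emitted volumes carry the configured distinct grids with overlapping extents", {
  cfg <- small_config()
  truth <- build_phantom(cfg)
  dce <- simulate_dce(cfg, truth); dwi <- simulate_dw(cfg, truth)
  expect_equal(dce$grid$voxel, c(1.44, 1.44, 2))
  expect_equal(dwi$grid$voxel, c(1.52, 1.52, 6))
  ea <- breastqmri:::grid_extent(dce$grid); eb <- breastqmri:::grid_extent(dwi$grid)
  expect_true(all(pmin(ea["hi", ], eb["hi", ]) > pmax(ea["lo", ], eb["lo", ])))
  # every lesion present on both grids with finite parameters
  expect_setequal(unique(as.vector(truth$mask_dce)), c(0L, truth$lesions$lesion_id))
  les <- which(truth$mask_dce > 0)
  expect_true(all(is.finite(truth$tofts_dce$ktrans[les])))
})
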