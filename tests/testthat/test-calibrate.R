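make_calset <- function(scene_arr, bright_arr, dark_arr, r_ref = 0.10,
                        grid = NULL) {
  if (is.null(grid))
    grid <- build_wavelength_grid(420, 420 + 5 * (dim(scene_arr)[3] - 1), 5)
  calibration_set(hypercube(scene_arr, grid),
                  hypercube(bright_arr, grid),
                  hypercube(dark_arr, grid), r_ref = r_ref)
}

test_that("the two-point transform reproduces its algebraic identities", {
  dims <- c(5, 6, 4)
  bright <- array(8000, dims)
  dark <- array(0, dims)
  # I = I_ref, I_d = 0  ->  R == R_ref everywhere
  cs <- make_calset(bright, bright, dark)
  r <- reflectance_transform(cs)
  expect_equal(as.vector(r$data), rep(0.10, prod(dims)))
  # I = I_d  ->  R == 0
  dark2 <- array(500, dims)
  cs2 <- make_calset(dark2, bright, dark2)
  expect_equal(as.vector(reflectance_transform(cs2)$data),
               rep(0, prod(dims)))
})

test_that("ill-conditioned entries are flagged invalid, not zeroed", {
  dims <- c(4, 4, 3)
  bright <- array(8000, dims); dark <- array(100, dims)
  scene <- array(4000, dims)
  bright[2, 3, 1] <- 100                      # I_ref == I_d at one entry
  cs <- make_calset(scene, bright, dark)
  r <- reflectance_transform(cs)
  expect_true(is.na(r$data[2, 3, 1]))
  expect_false(r$mask[2, 3, 1])
  expect_equal(sum(!r$mask), 1L)
  expect_equal(r$data[1, 1, 1], 0.10 * 3900 / 7900)
})

test_that("saturated entries are masked and counted", {
  dims <- c(4, 4, 3)
  bright <- array(8000, dims); dark <- array(0, dims)
  scene <- array(4000, dims)
  scene[1, 1, 2] <- 2^14 - 1
  cs <- make_calset(scene, bright, dark)
  vm <- make_validity_mask(cs)
  expect_false(vm$valid[1, 1, 2])
  expect_equal(sum(!vm$valid), 1L)
  # all counts mid-range -> all valid
  expect_true(all(make_validity_mask(make_calset(array(4000, dims), bright,
                                                 dark))$valid))
})

test_that("simulated overexposure is flagged at the injected fraction", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.05, 0.9)     # drives the 0.45 panel into clip
  scn <- flat_patch_scene(patch_refl = 0.45)
  acq <- simulate_acquisition(scn, ins, plan, noise = FALSE)
  cs <- calibration_set(acq$scene, acq$bright, acq$dark)
  vm <- make_validity_mask(cs)
  injected <- mean(acq$scene$data >= 2^14 - 1 | acq$bright$data >= 2^14 - 1)
  expect_equal(mean(!vm$valid), injected)
  expect_gt(injected, 0)
})

test_that("negative numerators are clipped to zero and annotated", {
  dims <- c(3, 3, 2)
  bright <- array(8000, dims); dark <- array(100, dims)
  scene <- array(4000, dims)
  scene[1, 2, 1] <- 50                        # below dark level
  r <- reflectance_transform(make_calset(scene, bright, dark))
  expect_equal(r$data[1, 2, 1], 0)
  expect_true(r$mask[1, 2, 1])                # still usable
  expect_equal(r$flags[1, 2, 1], 3L)
  expect_equal(r$metadata$n_clipped, 1L)
})

test_that("noise-free forward-model round trip recovers flat patches exactly", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.6, 0.8)
  scn <- flat_patch_scene(patch_refl = 0.30)
  acq <- simulate_acquisition(scn, ins, plan, noise = FALSE)
  r <- reflectance_transform(calibration_set(acq$scene, acq$bright,
                                             acq$dark))
  expect_lt(max(abs(r$data[6, 6, ] - 0.30)), 1e-9)     # patch pixel
  expect_lt(max(abs(r$data[1, 1, ] - 0.45)), 1e-9)     # panel pixel
})

test_that("recovered reflectance is invariant to the illumination profile", {
  # multiplying the spatial profile of the source by any positive field
  # leaves the pixel-wise two-point recovery unchanged (flat-field property)
  plan <- plan_exposures(tiny_instrument(), 0.6, 0.8)
  recover <- function(tilt) {
    ins <- instrument_model(16, 20, tilt_falloff = tilt)
    scn <- flat_patch_scene()
    acq <- simulate_acquisition(scn, ins, plan, noise = FALSE)
    reflectance_transform(calibration_set(acq$scene, acq$bright,
                                          acq$dark))$data
  }
  expect_lt(max(abs(recover(0.35) - recover(2.0))), 1e-12)
})

test_that("recovery is invariant to per-channel exposure rescaling", {
  ins <- tiny_instrument()
  scn <- flat_patch_scene()
  plan1 <- plan_exposures(ins, 0.6, 0.8)
  plan2 <- plan1
  set.seed(8)
  plan2$t_exp <- plan1$t_exp * runif(63, 0.3, 0.9)
  rec <- function(p) {
    acq <- simulate_acquisition(scn, ins, p, noise = FALSE)
    reflectance_transform(calibration_set(acq$scene, acq$bright,
                                          acq$dark))$data
  }
  expect_lt(max(abs(rec(plan1) - rec(plan2))), 1e-12)
})

test_that("vectorized transform matches an entry-by-entry scalar oracle", {
  set.seed(21)
  dims <- c(8, 8, 5)
  dark <- array(runif(prod(dims), 0, 200), dims)
  bright <- dark + array(runif(prod(dims), 500, 9000), dims)
  scene <- dark + array(runif(prod(dims), -100, 8000), dims)
  scene <- pmax(scene, 0)
  r_ref <- 0.10
  cs <- make_calset(scene, bright, dark, r_ref = r_ref)
  got <- reflectance_transform(cs)$data
  oracle <- array(NA_real_, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (c in 1:dims[3]) {
    num <- scene[i, j, c] - dark[i, j, c]
    den <- bright[i, j, c] - dark[i, j, c]
    if (den <= 10) next
    if (num < 0) num <- 0
    oracle[i, j, c] <- (num / den) * r_ref
  }
  expect_identical(got, oracle)
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  grid <- build_wavelength_grid(420, 730, 5)
  wl <- grid$centers
  const_cube <- direct_refl_cube(3, 3, function(r, c) rep(0.25, 63), grid)
  sm <- smooth_spectra(const_cube)
  expect_equal(sm$data, const_cube$data, tolerance = 1e-12)
  quad <- 0.2 + 1e-4 * (wl - 575) + 2e-6 * (wl - 575)^2
  quad_cube <- direct_refl_cube(2, 2, function(r, c) quad, grid)
  smq <- smooth_spectra(quad_cube)
  # an order-2 filter reproduces any quadratic, interior and edges alike
  expect_equal(smq$data, quad_cube$data, tolerance = 1e-10)
  expect_equal(smq$grid$centers, wl)
  expect_equal(dim(smq$data), dim(quad_cube$data))
})

test_that("smoothing attenuates white noise by the filter's coefficient norm", {
  grid <- build_wavelength_grid(420, 730, 5)
  set.seed(31)
  n <- 4000
  noise <- matrix(rnorm(n * 63, 0, 0.02), n, 63)
  cube <- hypercube(aperm(array(t(0.3 + noise), c(63, 80, 50)), c(2, 3, 1)),
                    grid, kind = "reflectance")
  sm <- smooth_spectra(cube)
  mid <- 20:44                                  # interior channels
  var_pre <- var(as.vector(cube$data[, , mid] - 0.3))
  var_post <- var(as.vector(sm$data[, , mid] - 0.3))
  coef_mid <- signal::sgolay(p = 2, n = 9)[5, ]
  expect_equal(var_post / var_pre, sum(coef_mid^2), tolerance = 0.05)
})

test_that("smoothing rejects invalid windows and raw cubes", {
  grid <- build_wavelength_grid(420, 730, 5)
  cube <- direct_refl_cube(2, 2, function(r, c) runif(63), grid)
  expect_error(smooth_spectra(cube, window_channels = 8), "odd")
  expect_error(smooth_spectra(cube, poly_order = 3, window_channels = 3),
               "exceed")
  expect_error(smooth_spectra(cube, window_channels = 65), "channel count")
  raw <- hypercube(array(1, c(2, 2, 63)), grid, kind = "raw_counts")
  expect_error(smooth_spectra(raw), "reflectance")
})

test_that("smoothing keeps invalid entries flagged", {
  grid <- build_wavelength_grid(420, 730, 5)
  arr <- array(0.3, c(2, 2, 63))
  mask <- array(TRUE, dim(arr))
  arr[1, 1, 10] <- NA; mask[1, 1, 10] <- FALSE
  cube <- hypercube(arr, grid, kind = "reflectance", mask = mask)
  sm <- smooth_spectra(cube)
  expect_true(is.na(sm$data[1, 1, 10]))
  expect_false(sm$mask[1, 1, 10])
  expect_equal(sm$data[2, 2, ], rep(0.3, 63), tolerance = 1e-12)
})
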