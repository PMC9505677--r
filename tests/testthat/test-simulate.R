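test_that("LCTF passband endpoints match the published curves", {
  lctf <- lctf_model()
  fine <- seq(400, 750, by = 0.2)
  pb420 <- lctf_passband(lctf, 420, fine)
  pb730 <- lctf_passband(lctf, 730, fine)
  expect_equal(max(pb420), 0.0072, tolerance = 1e-12)
  expect_equal(max(pb730), 0.236, tolerance = 1e-12)
  measure_fwhm <- function(pb) {
    above <- fine[pb >= max(pb) / 2]
    max(above) - min(above)
  }
  expect_equal(measure_fwhm(pb420), 6.8, tolerance = 0.25)
  expect_equal(measure_fwhm(pb730), 14.4, tolerance = 0.25)
  # interpolated width at an interior CWL, measured numerically on the kernel
  pb575 <- lctf_passband(lctf, 575, fine)
  expected <- 6.8 + (14.4 - 6.8) * (575 - 420) / (730 - 420)
  expect_equal(measure_fwhm(pb575), expected, tolerance = 0.25)
  expect_error(lctf_passband(lctf, 410), "outside")
})

test_that("endmember spectra carry the class-diagnostic features", {
  f <- FINE_GRID_NM
  argmin_in <- function(refl, lo, hi) {
    w <- f >= lo & f <= hi
    f[w][which.min(refl[w])]
  }
  argmax_in <- function(refl, lo, hi) {
    w <- f >= lo & f <= hi
    f[w][which.max(refl[w])]
  }
  for (cl in c("green_algae", "brown_algae", "red_algae")) {
    em <- generate_endmember(cl)
    # chlorophyll-a absorption dips (window = feature position +/- spread)
    expect_true(abs(argmin_in(em$reflectance, 435, 465) - 450) <= 10,
                label = paste(cl, "450 nm dip"))
    expect_true(abs(argmin_in(em$reflectance, 648, 682) - 665) <= 15,
                label = paste(cl, "665 nm dip"))
    # fluorescence-plus-scattering peak near 720 nm
    expect_true(abs(argmax_in(em$reflectance, 695, 745) - 720) <= 15,
                label = paste(cl, "720 nm peak"))
    # dark organisms: low mean reflectance over 420-700 nm
    band <- f >= 420 & f <= 700
    expect_lt(mean(em$reflectance[band]), 0.16)
  }
  red <- generate_endmember("red_algae")
  expect_true(abs(argmin_in(red$reflectance, 601, 629) - 615) <= 15)
  expect_true(abs(argmax_in(red$reflectance, 575, 605) - 590) <= 10)
  expect_true(abs(argmax_in(red$reflectance, 626, 652) - 640) <= 15)
  green <- generate_endmember("green_algae")
  expect_true(abs(argmax_in(green$reflectance, 530, 560) - 545) <= 10)
  brown <- generate_endmember("brown_algae")
  expect_true(abs(argmax_in(brown$reflectance, 555, 588) - 570) <= 10)
  band <- f >= 420 & f <= 700
  white <- generate_endmember("panel_white")
  expect_equal(mean(white$reflectance[band]), 0.45, tolerance = 1e-9)
  expect_lt(diff(range(white$reflectance)), 1e-9)      # spectrally flat
  mussel <- generate_endmember("mussel")
  expect_equal(mean(mussel$reflectance[band]), 0.04, tolerance = 0.01)
  expect_error(generate_endmember("kelp_forest"), "unknown")
})

test_that("endmember generation is deterministic given a seed", {
  a <- generate_endmember("green_algae", seed = 5,
                          brightness_jitter_sd = 0.1, dip_jitter_sd = 0.2)
  b <- generate_endmember("green_algae", seed = 5,
                          brightness_jitter_sd = 0.1, dip_jitter_sd = 0.2)
  expect_identical(a$reflectance, b$reflectance)
  c <- generate_endmember("green_algae", seed = 6,
                          brightness_jitter_sd = 0.1, dip_jitter_sd = 0.2)
  expect_false(identical(a$reflectance, c$reflectance))
  # species share their color group's construction
  u <- generate_endmember("Ulva")
  g <- generate_endmember("green_algae")
  expect_identical(u$reflectance, g$reflectance)
})

test_that("scene generation gives exact ground-truth fractions", {
  em <- generate_endmember_set(c("panel_white", "green_algae"))
  # 2500 of 10000 pixels
  scn <- generate_scene(
    list(list(type = "rect", class = "green_algae",
              r0 = 0, r1 = 25, c0 = 0, c1 = 100)),
    100, 100, em, brightness_jitter_sd = 0, seed = 1)
  cov <- ground_truth_coverage(scn)
  expect_equal(unname(cov["green_algae"]), 25)
  expect_equal(unname(cov["panel_white"]), 75)
  # empty layout -> all panel
  empty <- generate_scene(list(), 10, 10, em, seed = 1)
  expect_equal(unname(ground_truth_coverage(empty)["panel_white"]), 100)
  # fixed seed -> identical scene
  s1 <- generate_scene(list(list(type = "ellipse", class = "green_algae",
                                 center = c(5, 5), radii = c(3, 4))),
                       12, 12, em, seed = 9)
  s2 <- generate_scene(list(list(type = "ellipse", class = "green_algae",
                                 center = c(5, 5), radii = c(3, 4))),
                       12, 12, em, seed = 9)
  expect_identical(s1$jitter, s2$jitter)
  expect_identical(s1$labels$labels, s2$labels$labels)
  # later shapes win on overlap
  s3 <- generate_scene(list(
    list(type = "rect", class = "green_algae", r0 = 0, r1 = 6, c0 = 0, c1 = 6),
    list(type = "rect", class = "panel_white", r0 = 0, r1 = 6, c0 = 0, c1 = 6)),
    6, 6, em, seed = 1)
  expect_equal(unname(ground_truth_coverage(s3)["panel_white"]), 100)
})

test_that("exposure planning scales linearly and peaks at spectral extremes", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.5, 0.5)
  ins2 <- instrument_model(16, 20, led_power = 2 * ins$led_power)
  plan2 <- plan_exposures(ins2, 0.5, 0.5)
  expect_equal(plan2$t_exp, plan$t_exp / 2, tolerance = 1e-12)
  plan_q <- plan_exposures(ins, 0.5, 0.25)
  expect_equal(plan$t_exp / plan_q$t_exp, rep(2, 63), tolerance = 1e-12)
  ctr <- ins$grid$centers
  expect_gt(plan$t_exp[ctr == 430], plan$t_exp[ctr == 550])
  expect_gt(plan$t_exp[ctr == 730], plan$t_exp[ctr == 600])
})

test_that("dark and degenerate scenes reproduce the model identities", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.6, 0.8)
  dark <- simulate_raw_cube(NULL, ins, plan, "dark", noise = FALSE)
  # per-channel: counts = t_exp * I_d exactly, every pixel
  for (ch in c(1L, 17L, 63L))
    expect_equal(as.vector(dark$data[, , ch]),
                 as.vector(ins$dark_current * plan$t_exp[ch]))
  # scene with R == 0 equals the dark cube
  em <- generate_endmember_set(c("panel_white", "panel_gray"))
  em$panel_white$reflectance[] <- 0
  zero <- generate_scene(list(), 16, 20, em, brightness_jitter_sd = 0,
                         seed = 1)
  sc <- simulate_raw_cube(zero, ins, plan, "scene", noise = FALSE)
  expect_equal(sc$data, dark$data)
  # scene with flat R == ref_reflectance equals the reference cube
  em$panel_white$reflectance[] <- 0.10
  flat <- generate_scene(list(), 16, 20, em, brightness_jitter_sd = 0,
                         seed = 1)
  sc10 <- simulate_raw_cube(flat, ins, plan, "scene", noise = FALSE)
  ref <- simulate_raw_cube(NULL, ins, plan, "reference",
                           ref_reflectance = 0.10, noise = FALSE)
  expect_equal(sc10$data, ref$data, tolerance = 1e-12)
})

test_that("noise-free counts are linear in exposure, gain and reflectance", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.6, 0.4)
  scn <- flat_patch_scene()
  base <- simulate_raw_cube(scn, ins, plan, noise = FALSE)
  dark <- simulate_raw_cube(NULL, ins, plan, "dark", noise = FALSE)
  sig <- base$data - dark$data
  # exposure doubled
  plan2 <- plan; plan2$t_exp <- plan$t_exp * 2
  dark2 <- simulate_raw_cube(NULL, ins, plan2, "dark", noise = FALSE)
  expect_equal(simulate_raw_cube(scn, ins, plan2, noise = FALSE)$data -
                 dark2$data, 2 * sig, tolerance = 1e-12)
  # gain doubled
  ins_g <- instrument_model(16, 20, em_gain = 40)
  dark_g <- simulate_raw_cube(NULL, ins_g, plan, "dark", noise = FALSE)
  expect_equal(simulate_raw_cube(scn, ins_g, plan, noise = FALSE)$data -
                 dark_g$data, 2 * sig, tolerance = 1e-12)
  # reflectance scaled by 0.5
  scn_h <- scn
  scn_h$endmember_matrix <- scn$endmember_matrix * 0.5
  expect_equal(simulate_raw_cube(scn_h, ins, plan, noise = FALSE)$data -
                 dark$data, 0.5 * sig, tolerance = 1e-12)
})

test_that("no simulated count exceeds the 14-bit ceiling", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.05, 0.9)     # gross overexposure of a 0.45 scene
  scn <- flat_patch_scene(patch_refl = 0.45)
  hot <- simulate_raw_cube(scn, ins, plan, noise = TRUE, seed = 1)
  expect_lte(max(hot$data), 2^14 - 1)
  expect_gte(min(hot$data), 0)
  expect_true(any(hot$data == 2^14 - 1))     # saturation actually reached
})

test_that("per-pixel SNR doubles when the exposure quadruples", {
  # shot-noise-limited reference acquisition, uniform illumination
  ins <- instrument_model(100, 100, tilt_falloff = 0, dark_current = 0,
                          read_noise_counts = 0)
  plan <- plan_exposures(ins, 0.5, 0.2)
  snr_one <- function(p, seed) {
    cube <- simulate_raw_cube(NULL, ins, p, "reference",
                              ref_reflectance = 0.10, noise = TRUE,
                              seed = seed)
    v <- cube$data[, , 30]
    mean(v) / sd(v)
  }
  p4 <- plan; p4$t_exp <- plan$t_exp * 4
  ratio <- snr_one(p4, 21) / snr_one(plan, 22)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("noisy simulation is reproducible for a fixed seed", {
  ins <- tiny_instrument()
  plan <- plan_exposures(ins, 0.6, 0.5)
  scn <- flat_patch_scene(jitter = 0.1, seed = 4)
  a <- simulate_raw_cube(scn, ins, plan, noise = TRUE, seed = 123)
  b <- simulate_raw_cube(scn, ins, plan, noise = TRUE, seed = 123)
  expect_identical(a$data, b$data)
})
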