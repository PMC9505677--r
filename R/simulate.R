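## Forward simulation: exposure planning and raw hypercube synthesis.

#' Plan per-channel exposure times
#'
#' A staring imager acquires each wavelength band in its own shot, so exposure
#' times can be adjusted channel by channel to counter the wavelength
#' dependence of filter transmission, source radiance, water absorption and
#' sensor responsivity. The planner chooses, for every channel, the exposure
#' at which the brightest pixel of a spectrally flat target of reflectance
#' `reference_reflectance` would reach `target_fill` of the saturation
#' ceiling (noise-free, signal term only). Exposures therefore come out much
#' larger at the spectral extremes than mid-band.
#'
#' @param instrument an [instrument_model()]
#' @param reference_reflectance flat reflectance used for the sizing (use the
#'   brightest reflectance expected in the scene to preclude saturation)
#' @param target_fill fraction of the ADC ceiling to aim for, in (0, 1)
#' @return object of class `exposure_plan`: `t_exp` (seconds per channel)
#' @export
plan_exposures <- function(instrument, reference_reflectance = 0.5,
                           target_fill = 0.8) {
  stopifnot(target_fill > 0, target_fill < 1, reference_reflectance > 0)
  W <- instrument_spectral_weights(instrument)
  s_chan <- colSums(W)                        # flat-spectrum channel weight
  if (any(s_chan <= 0))
    stop("channel with zero expected signal: cannot plan an exposure")
  peak_rate <- instrument$em_gain * max(instrument$profile) *
    reference_reflectance * s_chan
  t_exp <- target_fill * instrument$saturation / peak_rate
  structure(list(t_exp = t_exp, grid = instrument$grid,
                 target_fill = target_fill,
                 reference_reflectance = reference_reflectance),
            class = "exposure_plan")
}

#' @export
print.exposure_plan <- function(x, ...) {
  cat(sprintf("<exposure_plan> %d channels, t_exp %.3g-%.3g s (median %.3g s)\n",
              length(x$t_exp), min(x$t_exp), max(x$t_exp),
              stats::median(x$t_exp)))
  invisible(x)
}

#' Simulate a raw hypercube (scene, dark field, or bright field)
#'
#' Synthesizes camera counts channel by channel:
#' `counts = clip(t_exp * (I_d + G * sum_l I_s e^{-2 a d_w} R tau_TF tau_O
#' Resp dl) + noise, 0, 2^adc_bits - 1)`.
#' `mode = "dark"` zeroes the signal term (shutter closed); `mode =
#' "reference"` replaces the scene reflectance with the spatially flat
#' reflectance of a calibration standard. With `noise = FALSE` the output is
#' deterministic and unquantized, so algebraic identities hold exactly; with
#' noise on, shot noise (with the electron-multiplication excess factor
#' sqrt(2)), Poisson dark counts and Gaussian read noise are added and counts
#' are rounded to integers.
#'
#' @param scene a [generate_scene()] object (ignored in dark/reference modes)
#' @param instrument an [instrument_model()] whose frame matches the scene
#' @param plan an [plan_exposures()] object on the instrument's grid
#' @param mode `"scene"`, `"dark"` or `"reference"`
#' @param ref_reflectance reflectance of the calibration standard (default
#'   10%)
#' @param noise logical; add the stochastic noise model
#' @param seed integer seed used when `noise = TRUE`
#' @return a [hypercube()] of kind `raw_counts`
#' @export
simulate_raw_cube <- function(scene, instrument, plan,
                              mode = c("scene", "dark", "reference"),
                              ref_reflectance = 0.10,
                              noise = TRUE, seed = 1) {
  mode <- match.arg(mode)
  if (!grids_identical(plan$grid, instrument$grid))
    stop("exposure plan grid does not match instrument grid")
  if (any(plan$t_exp <= 0)) stop("exposure times must be positive")
  rows <- instrument$rows; cols <- instrument$cols
  nch <- length(instrument$grid$centers)
  npix <- rows * cols
  W <- instrument_spectral_weights(instrument)          # fine x channels

  if (mode == "scene") {
    if (is.null(scene)) stop("scene mode needs a scene")
    lab_dim <- dim(scene$labels$labels)
    if (lab_dim[1] != rows || lab_dim[2] != cols)
      stop("scene dimensions do not match instrument frame")
    # per-class channel signal, then expand by label + jitter
    M <- scene$endmember_matrix %*% W                    # classes x channels
    lab <- as.vector(t(scene$labels$labels))
    jit <- as.vector(t(scene$jitter))
    sig_pix <- M[lab, , drop = FALSE] * jit              # npix x channels
  } else if (mode == "reference") {
    sig_pix <- matrix(rep(ref_reflectance * colSums(W), each = npix),
                      npix, nch)
  } else {
    sig_pix <- matrix(0, npix, nch)
  }
  prof <- as.vector(t(instrument$profile))
  dark_rate <- as.vector(t(instrument$dark_current))
  G <- instrument$em_gain
  rate_signal <- G * prof * sig_pix                      # counts/s
  t_row <- rep(plan$t_exp, each = npix)
  mean_signal <- rate_signal * t_row
  mean_dark <- dark_rate * t_row

  if (noise) {
    set.seed(as.integer(seed))
    # output-node conversion (electrons per count): fixed so that at the
    # configured gain the ADC range spans the full pixel well, the setting
    # that exploits the sensor's dynamic range
    k_out <- instrument$em_gain * instrument$well_depth /
      instrument$saturation
    n_e <- mean_signal * k_out / G           # input-referred photoelectrons
    sig <- mean_signal + (G / k_out) * sqrt(2 * pmax(n_e, 0)) *
      stats::rnorm(npix * nch)
    drk <- stats::rpois(npix * nch, mean_dark)
    counts <- round(sig + drk +
                      stats::rnorm(npix * nch, 0, instrument$read_noise_counts))
  } else {
    counts <- mean_signal + mean_dark
  }
  counts <- pmin(pmax(counts, 0), instrument$saturation)
  arr <- pixel_matrix_to_array(matrix(counts, npix, nch), rows, cols)
  hypercube(arr, instrument$grid, kind = "raw_counts",
            metadata = list(mode = mode, noise = noise,
                            seed = if (noise) as.integer(seed) else NA_integer_,
                            saturation = instrument$saturation,
                            ref_reflectance = if (mode == "reference")
                              ref_reflectance else NA_real_))
}

#' Simulate the standard three-cube acquisition of one target
#'
#' Convenience wrapper producing the scene, bright-field (reference standard)
#' and dark-field cubes under one shared exposure plan, as the calibration
#' procedure requires.
#'
#' @inheritParams simulate_raw_cube
#' @param seed base seed; the three cubes use distinct sub-seeds
#' @return list with `scene`, `bright`, `dark` hypercubes and `plan`
#' @export
simulate_acquisition <- function(scene, instrument, plan,
                                 ref_reflectance = 0.10, noise = TRUE,
                                 seed = 1) {
  seed <- as.integer(seed)
  list(
    scene = simulate_raw_cube(scene, instrument, plan, "scene",
                              noise = noise, seed = seed),
    bright = simulate_raw_cube(NULL, instrument, plan, "reference",
                               ref_reflectance = ref_reflectance,
                               noise = noise, seed = seed + 1L),
    dark = simulate_raw_cube(NULL, instrument, plan, "dark",
                             noise = noise, seed = seed + 2L),
    plan = plan)
}
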