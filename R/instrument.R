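## Radiometric instrument model for the staring LCTF imager.
##
## The forward model composes, per tunable-filter setting (channel c with
## center wavelength lambda_c):
##
##   I(x,y,c) = t_exp(c) * [ I_d(x,y)
##              + G * sum_l I_s(x,y,l) e^{-2 a(l) d_w} R(x,y,l)
##                        tau_TF(l, lambda_c) tau_O(l) Resp(l) dl ]
##
## evaluated by trapezoid-like quadrature on a fine internal 1 nm grid.
## All spectral curves live on that fine grid.

FINE_GRID_NM <- seq(400, 750, by = 1)

# piecewise-linear curve helper over the fine grid
curve_on_fine <- function(x, y, fine = FINE_GRID_NM) {
  stats::approx(x, y, xout = fine, rule = 2)$y
}

#' Liquid crystal tunable filter model
#'
#' The filter's passband full width at half maximum (FWHM) and peak
#' transmission both increase monotonically with center wavelength over the
#' 420--730 nm operating range: FWHM from about 6.8 nm to about 14.4 nm, peak
#' transmission (unpolarized input) from about 0.72% to about 23.6%. Both are
#' interpolated linearly in CWL between the published endpoints; the passband
#' is a unit-peak Gaussian truncated at three standard deviations.
#'
#' @param range operating range in nm
#' @param fwhm_endpoints FWHM at the two range ends (nm)
#' @param peak_trans_endpoints peak transmission fraction at the range ends
#' @return object of class `lctf_model`
#' @export
lctf_model <- function(range = c(420, 730),
                       fwhm_endpoints = c(6.8, 14.4),
                       peak_trans_endpoints = c(0.0072, 0.236)) {
  stopifnot(all(fwhm_endpoints > 0), all(peak_trans_endpoints > 0),
            all(peak_trans_endpoints < 1),
            diff(fwhm_endpoints) >= 0, diff(peak_trans_endpoints) >= 0)
  structure(list(range = range, fwhm_endpoints = fwhm_endpoints,
                 peak_trans_endpoints = peak_trans_endpoints),
            class = "lctf_model")
}

lctf_fwhm <- function(lctf, cwl) {
  stats::approx(lctf$range, lctf$fwhm_endpoints, xout = cwl, rule = 2)$y
}

lctf_peak_transmission <- function(lctf, cwl) {
  stats::approx(lctf$range, lctf$peak_trans_endpoints, xout = cwl, rule = 2)$y
}

#' Discrete LCTF passband at one center wavelength
#'
#' @param lctf an [lctf_model()]
#' @param cwl center wavelength (nm), inside the filter range
#' @param fine fine wavelength grid (nm) on which to sample the passband
#' @return transmission fractions over `fine`; peak value equals the filter's
#'   peak transmission at `cwl`, measured FWHM equals the model FWHM to within
#'   one fine-grid step
#' @export
lctf_passband <- function(lctf, cwl, fine = FINE_GRID_NM) {
  if (cwl < lctf$range[1] || cwl > lctf$range[2])
    stop(sprintf("cwl %g nm outside filter range [%g, %g]",
                 cwl, lctf$range[1], lctf$range[2]))
  fwhm <- lctf_fwhm(lctf, cwl)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  kern <- exp(-0.5 * ((fine - cwl) / sigma)^2)
  kern[abs(fine - cwl) > 3 * sigma] <- 0
  kern * lctf_peak_transmission(lctf, cwl)
}

#' Water column model
#'
#' Two-way propagation through a water path of length `d_w` attenuates the
#' signal by `exp(-2 a(l) d_w)`. The built-in attenuation curve has a smooth
#' pure-water-like shape, near zero in the blue-green and rising steeply
#' toward 730 nm; any user table `(nm, 1/m)` overrides it.
#'
#' @param d_w one-way geometric path length in water (m); 0 disables water
#'   extinction
#' @param attenuation optional two-column matrix/data frame `(wavelength_nm,
#'   alpha_per_m)`
#' @param n_w refractive index of water (geometry bookkeeping only)
#' @return object of class `water_model` holding `alpha` on the fine grid
#' @export
water_model <- function(d_w = 0.4, attenuation = NULL, n_w = 1.33) {
  stopifnot(d_w >= 0)
  if (is.null(attenuation)) {
    anchors_nm <- c(400, 450, 500, 550, 600, 650, 700, 730, 750)
    anchors_a  <- c(0.007, 0.009, 0.02, 0.06, 0.22, 0.34, 0.65, 1.8, 2.4)
    alpha <- curve_on_fine(anchors_nm, anchors_a)
  } else {
    attenuation <- as.data.frame(attenuation)
    if (any(attenuation[[2]] < 0)) stop("attenuation must be nonnegative")
    alpha <- curve_on_fine(attenuation[[1]], attenuation[[2]])
  }
  structure(list(d_w = d_w, alpha = alpha, n_w = n_w), class = "water_model")
}

# White (4000 K) LED: narrow blue pump peak near 450 nm plus a broad phosphor
# band around 600 nm; radiance in arbitrary units (absolute scale is set by
# `led_power`).
default_led_spectrum <- function(fine = FINE_GRID_NM) {
  0.85 * exp(-0.5 * ((fine - 452) / 11)^2) +
    1.00 * exp(-0.5 * ((fine - 600) / 62)^2)
}

# EMCCD spectral responsivity: broad, peaking mid-band and declining toward
# both the blue and the NIR edge of the operating range.
default_responsivity <- function(fine = FINE_GRID_NM) {
  0.95 * exp(-0.5 * ((fine - 560) / 130)^2)
}

#' Full instrument model
#'
#' Bundles the spectral chain (LED source, water column, tunable filter,
#' objective transmission, sensor responsivity), the sensor electronics
#' (electron-multiplying gain, well depth, ADC resolution, dark current,
#' read noise) and the illumination spatial profile. The profile is separable:
#' uniform vertically and falling off horizontally toward the left of the
#' frame, emulating the inverse-square falloff of an illuminator tilted about
#' 15 degrees relative to the imaging axis.
#'
#' @param rows,cols frame size in pixels
#' @param grid channel [build_wavelength_grid()] (default 420--730 nm / 5 nm)
#' @param lctf an [lctf_model()]
#' @param water a [water_model()]
#' @param led_spectrum LED spectral radiance on the fine grid (arbitrary units)
#' @param led_power scalar multiplier on the LED radiance
#' @param tau_o objective lens transmission (scalar or fine-grid curve)
#' @param responsivity sensor responsivity on the fine grid (counts-rate units)
#' @param dark_current dark signal rate, counts/s (scalar or `rows x cols`)
#' @param em_gain electron multiplication gain G (>= 1)
#' @param well_depth pixel well depth in electrons
#' @param adc_bits ADC resolution; saturation ceiling is `2^adc_bits - 1`
#' @param read_noise_counts post-gain read noise, standard deviation in counts
#' @param tilt_falloff fractional distance increase across the frame used by
#'   the inverse-square horizontal profile (0 = uniform illumination)
#' @param fine fine internal wavelength grid (nm)
#' @return object of class `instrument_model`
#' @export
instrument_model <- function(rows, cols,
                             grid = build_wavelength_grid(420, 730, 5),
                             lctf = lctf_model(),
                             water = water_model(),
                             led_spectrum = default_led_spectrum(),
                             led_power = 6e5,
                             tau_o = 0.9,
                             responsivity = default_responsivity(),
                             dark_current = 40,
                             em_gain = 20,
                             well_depth = 26000,
                             adc_bits = 14,
                             read_noise_counts = 2,
                             tilt_falloff = 0.35,
                             fine = FINE_GRID_NM) {
  stopifnot(em_gain >= 1, well_depth > 0, adc_bits >= 1)
  if (length(tau_o) == 1L) tau_o <- rep(tau_o, length(fine))
  if (any(led_spectrum < 0) || any(tau_o < 0) || any(responsivity < 0))
    stop("spectral curves must be nonnegative")
  if (length(dark_current) == 1L)
    dark_current <- matrix(dark_current, rows, cols)
  stopifnot(identical(dim(dark_current), c(as.integer(rows), as.integer(cols))))
  # separable spatial profile: inverse-square in x, uniform in y
  x <- (seq_len(cols) - 1L) / max(cols - 1L, 1L)        # 0 = left, 1 = right
  hprof <- 1 / (1 + tilt_falloff * (1 - x))^2
  profile <- matrix(rep(hprof, each = rows), rows, cols)
  # per-channel passband matrix over the fine grid (fine x channels)
  passbands <- vapply(grid$centers, function(cw) lctf_passband(lctf, cw, fine),
                      numeric(length(fine)))
  structure(list(rows = rows, cols = cols, grid = grid, lctf = lctf,
                 water = water, led_spectrum = led_spectrum,
                 led_power = led_power, tau_o = tau_o,
                 responsivity = responsivity, dark_current = dark_current,
                 em_gain = em_gain, well_depth = well_depth,
                 adc_bits = adc_bits,
                 saturation = 2^adc_bits - 1,
                 read_noise_counts = read_noise_counts,
                 profile = profile, passbands = passbands, fine = fine),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(paste0("<instrument_model> %d x %d px, %s\n",
                     "  G = %g, well %g e-, %d-bit ADC (ceiling %d), d_w = %g m\n"),
              x$rows, x$cols, format(x$grid), x$em_gain, x$well_depth,
              x$adc_bits, x$saturation, x$water$d_w))
  invisible(x)
}

# Per-channel spectral weights W[l, c] = I_s(l) e^{-2 a d} tau_TF(l,c)
# tau_O(l) Resp(l) dl, so that the signal rate for reflectance spectrum R is
# G * profile * (R . W[, c]). Quadrature: rectangle rule on the uniform fine
# grid (equivalent to trapezoid away from truncated kernel ends).
instrument_spectral_weights <- function(ins) {
  dl <- ins$fine[2] - ins$fine[1]
  atten <- exp(-2 * ins$water$alpha * ins$water$d_w)
  base <- ins$led_power * ins$led_spectrum * atten * ins$tau_o * ins$responsivity
  ins$passbands * base * dl           # fine x channels
}
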