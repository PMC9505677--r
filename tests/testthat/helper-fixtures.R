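# Shared fixtures: small instruments and scenes built in code.

tiny_instrument <- function(rows = 16, cols = 20, ...) {
  instrument_model(rows, cols, ...)
}

# two-class scene: flat gray patch on a white panel (both spectrally flat,
# so calibration recovery is passband-exact)
flat_patch_scene <- function(rows = 16, cols = 20, patch_refl = 0.30,
                             jitter = 0, seed = 2) {
  em <- generate_endmember_set(c("panel_white", "panel_gray"))
  em$panel_gray$reflectance[] <- patch_refl
  generate_scene(
    list(list(type = "rect", class = "panel_gray",
              r0 = 4, r1 = 12, c0 = 4, c1 = 16)),
    rows, cols, em, brightness_jitter_sd = jitter, seed = seed)
}

# library of well-separated Gaussian blobs in spectral space
blob_library <- function(n_per_class = 60, n_channels = 12, k = 3,
                         sep = 6, noise_sd = 0.3, seed = 99) {
  set.seed(seed)
  grid <- build_wavelength_grid(420, 420 + 5 * (n_channels - 1), 5)
  centers <- matrix(rnorm(k * n_channels), k) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rep(centers[i, ], each = n_per_class), n_per_class) +
      matrix(rnorm(n_per_class * n_channels, 0, noise_sd), n_per_class)))
  labels <- rep(sprintf("class_%d", seq_len(k)), each = n_per_class)
  spectral_library(x, labels, grid)
}

# quick WNN config for unit tests (small net, fewer iterations)
quick_wnn <- function(...) {
  args <- utils::modifyList(list(hidden_units = 25, maxit = 150),
                            list(...))
  do.call(wnn_config, args)
}

# a calibrated reflectance cube built directly (no simulator)
direct_refl_cube <- function(rows, cols, spectra_fn, grid =
                               build_wavelength_grid(420, 730, 5)) {
  nch <- length(grid$centers)
  arr <- array(0, c(rows, cols, nch))
  for (r in seq_len(rows)) for (c in seq_len(cols))
    arr[r, c, ] <- spectra_fn(r, c)
  hypercube(arr, grid, kind = "reflectance")
}
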