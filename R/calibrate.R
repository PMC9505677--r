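## Two-point pixel-wise reflectance calibration and spectral smoothing.
##
## Three cubes acquired under one exposure plan — scene I, bright field I_ref
## (a diffuse standard of known reflectance R_ref, default 10%), and dark
## field I_d — determine per pixel and channel:
##
##     R(x,y,l) = R_ref(l) * (I - I_d) / (I_ref - I_d)
##
## Because the transform is computed at pixel level from the same location in
## all three cubes, it simultaneously performs the flat-field correction:
## any spatial non-uniformity of illumination or filter transmission cancels.

# flag codes for per-entry conditions
FLAG_VALID <- 0L
FLAG_SATURATED <- 1L
FLAG_UNDEREXPOSED <- 2L
FLAG_CLIPPED_NEGATIVE <- 3L

#' Bundle the three cubes of a calibration acquisition
#'
#' @param scene,bright,dark raw-count [hypercube()]s of identical dimensions,
#'   grid and exposure plan
#' @param r_ref reference-standard reflectance: a scalar in (0, 1] or a
#'   per-channel vector
#' @return object of class `calibration_set`
#' @export
calibration_set <- function(scene, bright, dark, r_ref = 0.10) {
  for (cb in list(scene, bright, dark)) {
    stopifnot(inherits(cb, "hypercube"))
    if (cb$kind != "raw_counts") stop("calibration cubes must be raw counts")
  }
  if (!identical(dim(scene$data), dim(bright$data)) ||
      !identical(dim(scene$data), dim(dark$data)))
    stop("the three cubes must be dimensionally identical")
  if (!grids_identical(scene$grid, bright$grid) ||
      !grids_identical(scene$grid, dark$grid))
    stop("the three cubes must share one wavelength grid")
  nch <- dim(scene$data)[3]
  if (length(r_ref) == 1L) r_ref <- rep(r_ref, nch)
  if (length(r_ref) != nch) stop("r_ref must be scalar or per-channel")
  if (any(r_ref <= 0) || any(r_ref > 1))
    stop("r_ref must lie in (0, 1]")
  structure(list(scene = scene, bright = bright, dark = dark, r_ref = r_ref),
            class = "calibration_set")
}

cube_saturation <- function(cube, default = 2^14 - 1) {
  s <- cube$metadata$saturation
  if (is.null(s) || is.na(s)) default else s
}

#' Per-entry validity flags for a calibration set
#'
#' Flags entries that are saturated in the scene or bright cube (counts at or
#' above the ADC ceiling) or underexposed (bright minus dark below
#' `epsilon`, leaving the reflectance ratio ill-conditioned).
#'
#' @param calset a [calibration_set()]
#' @param epsilon minimum usable bright-minus-dark difference, in counts
#' @return list with integer `flags` array (codes 0 valid, 1 saturated,
#'   2 underexposed) and logical `valid` array
#' @export
make_validity_mask <- function(calset, epsilon = 10) {
  ceiling_counts <- cube_saturation(calset$scene)
  flags <- array(FLAG_VALID, dim = dim(calset$scene$data))
  denom <- calset$bright$data - calset$dark$data
  flags[denom <= epsilon] <- FLAG_UNDEREXPOSED
  flags[calset$scene$data >= ceiling_counts |
          calset$bright$data >= ceiling_counts] <- FLAG_SATURATED
  list(flags = flags, valid = flags == FLAG_VALID)
}

#' Transform raw counts to pixel-wise reflectance
#'
#' Applies the two-point transform independently per pixel and channel.
#' Entries with an ill-conditioned denominator or saturated counts are marked
#' invalid (never silently zeroed); negative numerators — possible under
#' noise when scene counts drop below the dark level — are clipped to zero
#' and annotated with their own flag while remaining usable.
#'
#' @param calset a [calibration_set()]
#' @param epsilon denominator guard in counts (see [make_validity_mask()])
#' @return reflectance [hypercube()] carrying `mask` (logical validity) and
#'   `flags` (condition codes)
#' @export
reflectance_transform <- function(calset, epsilon = 10) {
  vm <- make_validity_mask(calset, epsilon = epsilon)
  num <- calset$scene$data - calset$dark$data
  den <- calset$bright$data - calset$dark$data
  flags <- vm$flags
  neg <- num < 0 & vm$valid
  num[num < 0] <- 0
  flags[neg] <- FLAG_CLIPPED_NEGATIVE
  refl <- num / den
  nch <- dim(refl)[3]
  for (c in seq_len(nch)) refl[, , c] <- refl[, , c] * calset$r_ref[c]
  usable <- flags == FLAG_VALID | flags == FLAG_CLIPPED_NEGATIVE
  refl[!usable] <- NA_real_
  hypercube(refl, calset$scene$grid, kind = "reflectance",
            metadata = c(calset$scene$metadata,
                         list(r_ref = calset$r_ref[1], epsilon = epsilon,
                              n_invalid = sum(!usable),
                              n_clipped = sum(neg))),
            mask = usable, flags = flags)
}

# full Savitzky-Golay smoothing matrix for a spectrum of length nch:
# interior channels use the central projection row; the first and last
# half-windows use the corresponding off-center rows, i.e. a polynomial fit
# within the edge window (signal::sgolay provides all rows).
sg_smoothing_matrix <- function(poly_order, window, nch) {
  Fm <- signal::sgolay(p = poly_order, n = window)
  h <- (window - 1L) / 2L
  S <- matrix(0, nch, nch)
  mid <- Fm[h + 1L, ]
  for (i in seq_len(nch)) {
    if (i <= h) S[i, 1:window] <- Fm[i, ]
    else if (i > nch - h) S[i, (nch - window + 1L):nch] <- Fm[window - (nch - i), ]
    else S[i, (i - h):(i + h)] <- mid
  }
  S
}

#' Savitzky-Golay smoothing of a reflectance cube along the spectral axis
#'
#' Low-pass filters each pixel spectrum with a Savitzky-Golay filter
#' (default: second order, nine-channel window — 45 nm at 5 nm sampling),
#' smoothing noise without substantially altering broad spectral features.
#' Spatial dimensions are untouched. Edge channels are fitted with the
#' polynomial of the first/last window rather than padded. Invalid entries
#' are bridged by linear interpolation before filtering and remain flagged
#' invalid afterwards.
#'
#' @param refl_cube reflectance [hypercube()]
#' @param poly_order polynomial order (default 2)
#' @param window_channels odd window length, > `poly_order` and <= channel
#'   count (default 9)
#' @return smoothed reflectance [hypercube()], same grid, mask and flags
#' @export
smooth_spectra <- function(refl_cube, poly_order = 2, window_channels = 9) {
  if (refl_cube$kind != "reflectance")
    stop("smoothing operates on calibrated (reflectance) cubes")
  nch <- dim(refl_cube$data)[3]
  if (window_channels %% 2 == 0) stop("window must be odd")
  if (window_channels <= poly_order) stop("window must exceed the polynomial order")
  if (window_channels > nch) stop("window exceeds channel count")
  d <- dim(refl_cube$data)
  X <- cube_pixel_matrix(refl_cube)
  # bridge invalid entries so the filter has finite input
  bad <- !is.finite(X)
  if (any(bad)) {
    for (i in which(rowSums(bad) > 0L)) {
      xi <- X[i, ]
      ok <- is.finite(xi)
      X[i, ] <- if (sum(ok) >= 2L)
        stats::approx(which(ok), xi[ok], xout = seq_len(nch), rule = 2)$y
      else if (sum(ok) == 1L) rep(xi[ok], nch) else 0
    }
  }
  S <- sg_smoothing_matrix(poly_order, window_channels, nch)
  Y <- X %*% t(S)
  Y[bad] <- NA_real_
  out <- refl_cube
  out$data <- pixel_matrix_to_array(Y, d[1], d[2])
  out$metadata$smoothing <- sprintf(
    "savitzky-golay p=%d n=%d, edge=polynomial-fit", poly_order,
    window_channels)
  out
}
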