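## Endmember spectra of biofouling classes and coated panels.
##
## Each class reflectance is built as a flat-or-sloped baseline plus Gaussian
## reflectance peaks minus Gaussian absorption dips, on the fine 1 nm grid.
## Feature placement follows the optical signatures of the field classes:
## chlorophyll-a absorption dips near 450 and 665 nm in all algae, a red-algae
## satellite dip near 615 nm, an autofluorescence-plus-scattering peak near
## 720 nm (strongest in red algae), a green-algae reflectance peak near
## 545 nm, a brown-algae peak near 570 nm with a flatter and darker spectrum,
## red-algae peaks near 590 and 640 nm, a white panel near 45% flat
## reflectance, and mussels near 4% with a slight rise toward the red.

gauss_feature <- function(fine, center, sigma) {
  exp(-0.5 * ((fine - center) / sigma)^2)
}

# class -> construction parameters
endmember_params <- function(class) {
  p <- switch(class,
    green_algae = list(
      base = c(0.055, 0.055),
      peaks = list(c(545, 0.075, 16), c(720, 0.095, 11)),
      dips  = list(c(450, 0.032, 12), c(665, 0.036, 11))),
    brown_algae = list(
      base = c(0.045, 0.045),
      peaks = list(c(570, 0.035, 22), c(720, 0.075, 11)),
      dips  = list(c(450, 0.026, 12), c(665, 0.030, 11))),
    red_algae = list(
      base = c(0.050, 0.050),
      peaks = list(c(590, 0.055, 12), c(640, 0.048, 11), c(720, 0.140, 11)),
      dips  = list(c(450, 0.032, 12), c(615, 0.020, 9), c(665, 0.042, 10))),
    mussel = list(
      base = c(0.030, 0.052),        # slight brownish rise toward the red
      peaks = list(), dips = list()),
    barnacle = list(
      base = c(0.120, 0.120),
      peaks = list(c(720, 0.030, 11)),
      dips  = list(c(665, 0.015, 11))),
    panel_white = list(base = c(0.45, 0.45), peaks = list(), dips = list()),
    panel_gray  = list(base = c(0.20, 0.20), peaks = list(), dips = list()),
    panel_red   = list(base = c(0.06, 0.06),
                       peaks = list(c(645, 0.30, 26)), dips = list()),
    panel_blue  = list(base = c(0.06, 0.06),
                       peaks = list(c(455, 0.28, 24)), dips = list()),
    panel_blue_fcc = list(base = c(0.06, 0.06),
                          peaks = list(c(455, 0.28, 24), c(720, 0.05, 11)),
                          dips = list()),
    stop("unknown endmember class: ", class))
  p
}

# species of the fine grouping share their color group's spectral build;
# they differ only through realization jitter
fine_species_map <- c(
  Ulva = "green_algae", Zostera = "green_algae",
  Ceramium = "red_algae",
  Petalonia = "brown_algae", Scytosiphon = "brown_algae",
  Chorda = "brown_algae", Desmarestia = "brown_algae",
  Dictyosiphon = "brown_algae")

#' Known endmember classes
#' @return character vector of class names accepted by [generate_endmember()]
#' @export
endmember_classes <- function() {
  c("green_algae", "brown_algae", "red_algae", "mussel", "barnacle",
    "panel_white", "panel_gray", "panel_red", "panel_blue", "panel_blue_fcc",
    names(fine_species_map))
}

#' Generate one endmember reflectance spectrum
#'
#' Deterministic for a given class and seed. With nonzero jitter the realized
#' curve varies: the overall brightness is scaled by a log-normal factor and
#' each absorption-dip depth by its own log-normal factor. Species-level
#' classes (e.g. `"Ulva"`, `"Petalonia"`) reuse their color group's spectral
#' construction, so two species of one group differ only by jitter.
#'
#' @param class class name, see [endmember_classes()]
#' @param seed integer seed; `NULL` with zero jitter gives the nominal curve
#' @param brightness_jitter_sd log-scale s.d. of the overall brightness factor
#' @param dip_jitter_sd log-scale s.d. of the per-dip depth factors
#' @param fine fine wavelength grid (nm)
#' @return object of class `endmember_spectrum`: `class`, `reflectance`
#'   (nonnegative, on `fine`), `fine`
#' @export
generate_endmember <- function(class, seed = NULL,
                               brightness_jitter_sd = 0,
                               dip_jitter_sd = 0,
                               fine = FINE_GRID_NM) {
  base_class <- if (class %in% names(fine_species_map))
    fine_species_map[[class]] else class
  p <- endmember_params(base_class)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  } else if (brightness_jitter_sd > 0 || dip_jitter_sd > 0) {
    stop("jittered endmembers need a seed for reproducibility")
  }
  bright <- if (brightness_jitter_sd > 0)
    exp(stats::rnorm(1, 0, brightness_jitter_sd)) else 1
  refl <- stats::approx(c(fine[1], fine[length(fine)]), p$base,
                        xout = fine)$y
  for (pk in p$peaks)
    refl <- refl + pk[2] * gauss_feature(fine, pk[1], pk[3])
  for (dp in p$dips) {
    depth <- dp[2] * if (dip_jitter_sd > 0)
      exp(stats::rnorm(1, 0, dip_jitter_sd)) else 1
    refl <- refl - depth * gauss_feature(fine, dp[1], dp[3])
  }
  refl <- pmax(refl * bright, 0.002)
  structure(list(class = class, reflectance = refl, fine = fine,
                 params = p), class = "endmember_spectrum")
}

#' @export
print.endmember_spectrum <- function(x, ...) {
  band <- x$fine >= 420 & x$fine <= 700
  cat(sprintf("<endmember_spectrum> %s, mean reflectance 420-700 nm: %.3f\n",
              x$class, mean(x$reflectance[band])))
  invisible(x)
}

#' Generate a named set of endmembers
#' @param classes class names
#' @param seed base seed; each class uses a deterministic sub-seed
#' @param ... passed to [generate_endmember()]
#' @return named list of `endmember_spectrum`
#' @export
generate_endmember_set <- function(classes, seed = 1, ...) {
  out <- lapply(seq_along(classes), function(i) {
    sub_seed <- (as.numeric(seed) + 99991 * i) %% (.Machine$integer.max - 1)
    generate_endmember(classes[i], seed = as.integer(sub_seed), ...)
  })
  names(out) <- classes
  out
}
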