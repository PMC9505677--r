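## Synthetic model-target scenes: a coated panel background bearing patches of
## biofouling, with exact ground truth for coverage and classification tests.

rasterize_shape <- function(shape, rows, cols) {
  if (shape$type == "rect") {
    if (shape$r0 < 0 || shape$c0 < 0 || shape$r1 > rows || shape$c1 > cols)
      stop("rectangle outside frame")
    m <- matrix(FALSE, rows, cols)
    m[(shape$r0 + 1L):shape$r1, (shape$c0 + 1L):shape$c1] <- TRUE
    m
  } else if (shape$type == "ellipse") {
    rc <- matrix(0, rows, cols)
    r <- row(rc) - 1L; c <- col(rc) - 1L
    ((r - shape$center[1]) / shape$radii[1])^2 +
      ((c - shape$center[2]) / shape$radii[2])^2 <= 1
  } else stop("unknown shape type: ", shape$type)
}

#' Generate a synthetic fouled-panel scene
#'
#' Shapes are drawn onto a panel background in order (later shapes win where
#' they overlap). Each labeled pixel receives the realized reflectance of its
#' class endmember scaled by a per-pixel log-normal brightness factor, which
#' emulates within-class variability (density, orientation, health status).
#'
#' @param layout list of shapes; each is a list with `class` and either
#'   `type = "rect"` with 0-based half-open `r0`, `r1`, `c0`, `c1`, or
#'   `type = "ellipse"` with `center = c(row, col)` and `radii = c(rr, rc)`
#' @param rows,cols frame size
#' @param endmembers named list of [generate_endmember()] spectra covering the
#'   background and every class used in `layout`
#' @param background panel class name used where no shape is drawn
#' @param brightness_jitter_sd per-pixel log-normal brightness s.d.; 0 gives a
#'   scene whose every same-class pixel has an identical spectrum
#' @param seed integer seed for the jitter field
#' @return object of class `scene_map`: `labels` ([label_map()] ground truth),
#'   `classes` (code order), `endmembers`, `jitter` (`rows x cols`), `fine`
#' @export
generate_scene <- function(layout, rows, cols, endmembers,
                           background = "panel_white",
                           brightness_jitter_sd = 0.08, seed = 1) {
  classes <- unique(c(background, vapply(layout, `[[`, "", "class")))
  missing <- setdiff(classes, names(endmembers))
  if (length(missing))
    stop("no endmember for class(es): ", paste(missing, collapse = ", "))
  labels <- matrix(1L, rows, cols)            # background code 1
  for (shape in layout) {
    code <- match(shape$class, classes)
    m <- rasterize_shape(shape, rows, cols)
    labels[m] <- code
  }
  set.seed(as.integer(seed))
  jitter <- if (brightness_jitter_sd > 0)
    matrix(exp(stats::rnorm(rows * cols, 0, brightness_jitter_sd)), rows, cols)
  else matrix(1, rows, cols)
  legend <- stats::setNames(classes, as.character(seq_along(classes)))
  fine <- endmembers[[classes[1]]]$fine
  E <- t(vapply(classes, function(cl) endmembers[[cl]]$reflectance,
                numeric(length(fine))))
  structure(list(labels = label_map(labels, legend), classes = classes,
                 endmember_matrix = E, endmembers = endmembers[classes],
                 jitter = jitter, fine = fine, seed = seed),
            class = "scene_map")
}

#' @export
print.scene_map <- function(x, ...) {
  cov <- ground_truth_coverage(x)
  cat(sprintf("<scene_map> %d x %d px, %d classes\n",
              nrow(x$labels$labels), ncol(x$labels$labels), length(x$classes)))
  for (i in seq_along(cov))
    cat(sprintf("  %-16s %6.2f%%\n", names(cov)[i], cov[i]))
  invisible(x)
}

#' Exact ground-truth coverage fractions of a scene
#' @param scene a [generate_scene()] object
#' @return named percentages summing to 100
#' @export
ground_truth_coverage <- function(scene) {
  tab <- tabulate(scene$labels$labels, nbins = length(scene$classes))
  stats::setNames(100 * tab / sum(tab), scene$classes)
}

# realized per-pixel reflectance, pixels (row-major) x fine wavelengths
scene_reflectance_matrix <- function(scene) {
  lab <- as.vector(t(scene$labels$labels))     # row-major pixel order
  jit <- as.vector(t(scene$jitter))
  scene$endmember_matrix[lab, , drop = FALSE] * jit
}
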