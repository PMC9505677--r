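## Annotated spectral libraries: the training substrate of the classifier.

#' Construct a spectral library
#'
#' @param spectra numeric matrix, samples x channels
#' @param labels character vector of class names, one per sample
#' @param grid the shared [build_wavelength_grid()]
#' @param provenance data frame with one row per sample; columns `cube_id`,
#'   `row`, `col`, `roi_id`
#' @param scheme `"coarse"` or `"fine"` annotation scheme
#' @return object of class `spectral_library`
#' @export
spectral_library <- function(spectra, labels, grid, provenance = NULL,
                             scheme = c("coarse", "fine")) {
  scheme <- match.arg(scheme)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(grid$centers))
    stop("spectrum length does not match grid")
  if (length(labels) != nrow(spectra))
    stop("one label per sample required")
  if (any(!nzchar(labels))) stop("labels must be non-empty")
  if (is.null(provenance))
    provenance <- data.frame(cube_id = "unknown", row = NA_integer_,
                             col = NA_integer_, roi_id = NA_integer_,
                             stringsAsFactors = FALSE)[rep(1L, nrow(spectra)), ]
  structure(list(spectra = spectra, labels = as.character(labels),
                 grid = grid, provenance = provenance, scheme = scheme),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d samples, %d channels, scheme = %s\n",
              nrow(x$spectra), ncol(x$spectra), x$scheme))
  print(table(x$labels))
  invisible(x)
}

#' Harvest labeled pixel spectra from a calibrated cube
#'
#' Every valid pixel enclosed by each ROI becomes one library sample carrying
#' the ROI's class label; pixels with any invalid channel are skipped and
#' counted. Pixel order within each ROI is row-major, so assembly is
#' deterministic.
#'
#' @param refl_cube calibrated reflectance [hypercube()]
#' @param roiset a [roi_set()]
#' @param scheme annotation scheme recorded on the library
#' @return a [spectral_library()]; attribute `n_skipped` counts pixels
#'   dropped for invalid entries
#' @export
annotate <- function(refl_cube, roiset, scheme = "coarse") {
  if (refl_cube$kind != "reflectance")
    stop("annotation requires a calibrated (reflectance) cube")
  spectra <- list(); labels <- list(); prov <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(roiset))) {
    roi <- roiset[i, ]
    px <- extract_roi_pixels(refl_cube, roi)
    keep <- rowSums(!is.finite(px$spectra)) == 0L
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) next
    spectra[[length(spectra) + 1L]] <- px$spectra[keep, , drop = FALSE]
    labels[[length(labels) + 1L]] <- rep(roi$label, sum(keep))
    prov[[length(prov) + 1L]] <- data.frame(
      cube_id = roi$cube_id, row = px$coords$row[keep],
      col = px$coords$col[keep], roi_id = i, stringsAsFactors = FALSE)
  }
  if (!length(spectra)) stop("no valid pixels in any ROI")
  lib <- spectral_library(do.call(rbind, spectra), unlist(labels),
                          refl_cube$grid, do.call(rbind, prov),
                          scheme = scheme)
  attr(lib, "n_skipped") <- n_skipped
  lib
}

#' Map fine (species-level) labels to coarse (group-level) labels
#'
#' @param library a [spectral_library()]
#' @param mapping named character vector, `fine label -> coarse label`; must
#'   cover every label present
#' @return relabeled library (`scheme = "coarse"`); sample count and spectra
#'   are preserved exactly
#' @export
regroup <- function(library, mapping) {
  unmapped <- setdiff(unique(library$labels), names(mapping))
  if (length(unmapped))
    stop("mapping misses label(s): ", paste(unmapped, collapse = ", "))
  out <- library
  out$labels <- unname(mapping[library$labels])
  out$scheme <- "coarse"
  out
}

#' Default species -> color-group mapping
#'
#' Algae species map to their color group (e.g. Ulva and Zostera to green
#' algae, Ceramium to red, Petalonia/Scytosiphon/Chorda/Desmarestia/
#' Dictyosiphon to brown); animals map to themselves and all panel colors
#' merge into a single panel class.
#'
#' @return named character vector usable with [regroup()]
#' @export
default_class_mapping <- function() {
  c(fine_species_map,
    green_algae = "green_algae", red_algae = "red_algae",
    brown_algae = "brown_algae",
    mussel = "mussel", barnacle = "barnacle",
    panel_white = "panel", panel_gray = "panel", panel_red = "panel",
    panel_blue = "panel", panel_blue_fcc = "panel", panel = "panel")
}

#' Per-class mean and standard-deviation signatures
#'
#' @param library a [spectral_library()]
#' @return object of class `class_summary`: per class, `mean` and `sd`
#'   spectra plus sample counts (counts sum to the library size)
#' @export
summarize_library <- function(library) {
  classes <- sort(unique(library$labels))
  means <- sds <- matrix(NA_real_, length(classes), ncol(library$spectra),
                         dimnames = list(classes, NULL))
  counts <- integer(length(classes))
  for (i in seq_along(classes)) {
    rows <- library$labels == classes[i]
    if (!any(rows)) stop("empty class: ", classes[i])
    x <- library$spectra[rows, , drop = FALSE]
    means[i, ] <- colMeans(x)
    sds[i, ] <- if (nrow(x) > 1L) apply(x, 2L, stats::sd) else 0
    counts[i] <- nrow(x)
  }
  structure(list(classes = classes, mean = means, sd = sds,
                 count = stats::setNames(counts, classes),
                 grid = library$grid),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary>\n")
  for (i in seq_along(x$classes))
    cat(sprintf("  %-16s n = %6d, mean refl %.3f\n", x$classes[i],
                x$count[i], mean(x$mean[i, ])))
  invisible(x)
}

#' Split a library into spatially disjoint train and test partitions
#'
#' Samples are partitioned by their provenance cube so that no cube
#' contributes to both sides — guarding against leakage through correlated
#' neighboring pixels.
#'
#' @param library a [spectral_library()]
#' @param train_cubes,test_cubes disjoint sets of cube ids
#' @return list of two libraries, `train` and `test`
#' @export
split_spatially_disjoint <- function(library, train_cubes, test_cubes) {
  if (length(intersect(train_cubes, test_cubes)))
    stop("cube id(s) requested in both partitions: ",
         paste(intersect(train_cubes, test_cubes), collapse = ", "))
  pick <- function(cubes) {
    idx <- library$provenance$cube_id %in% cubes
    spectral_library(library$spectra[idx, , drop = FALSE],
                     library$labels[idx], library$grid,
                     library$provenance[idx, , drop = FALSE],
                     scheme = library$scheme)
  }
  list(train = pick(train_cubes), test = pick(test_cubes))
}

#' Read / write a spectral library as tabular text
#'
#' One row per sample: the per-channel reflectances, then `label`,
#' `cube_id`, `row`, `col`, `roi_id`.
#' @param library a [spectral_library()]
#' @param path CSV path
#' @export
write_library <- function(library, path) {
  df <- as.data.frame(library$spectra)
  names(df) <- sprintf("r%g", library$grid$centers)
  df$label <- library$labels
  df <- cbind(df, library$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @param grid grid to attach; reconstructed from column names when `NULL`
#' @export
read_library <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spec_cols <- grep("^r[0-9]", names(df))
  wl <- as.numeric(sub("^r", "", names(df)[spec_cols]))
  if (is.null(grid)) {
    step <- if (length(wl) > 1) wl[2] - wl[1] else 1
    grid <- build_wavelength_grid(wl[1], wl[length(wl)], step)
  }
  spectral_library(as.matrix(df[spec_cols]), df$label, grid,
                   df[c("cube_id", "row", "col", "roi_id")])
}
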