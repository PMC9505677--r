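## Standardized principal component analysis of library spectra: exploratory
## biplots and dimensionality reduction ahead of classification.

#' Fit a standardized PCA on library spectra
#'
#' Channels are mean-centered and variance-normalized using the training data
#' only; components are ordered by decreasing explained variance. A
#' deterministic sign convention — the largest-magnitude loading of each
#' component is made positive — keeps biplots reproducible across runs.
#' Channels with zero variance get unit scale and are flagged rather than
#' producing divisions by zero.
#'
#' @param x sample matrix (samples x channels) or a [spectral_library()]
#' @return object of class `hsi_pca`: `center`, `scale`, `rotation`
#'   (channels x components, orthonormal columns), `var_pct` (percent
#'   explained, descending, summing to 100), `zero_var_channels`,
#'   `n_selected` (initially all)
#' @export
fit_pca <- function(x) {
  if (inherits(x, "spectral_library")) x <- x$spectra
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least two samples")
  if (any(!is.finite(x))) stop("PCA input contains non-finite entries")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  zero_var <- which(scl == 0)
  scl[zero_var] <- 1
  pc <- stats::prcomp(x, center = ctr, scale. = scl)
  rot <- pc$rotation
  # sign convention: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  var <- pc$sdev^2
  structure(list(center = ctr, scale = scl, rotation = rot,
                 sdev = pc$sdev, var_pct = 100 * var / sum(var),
                 zero_var_channels = zero_var,
                 n_selected = ncol(rot)),
            class = "hsi_pca")
}

#' @export
print.hsi_pca <- function(x, ...) {
  cat(sprintf("<hsi_pca> %d channels -> %d components (%d selected)\n",
              nrow(x$rotation), ncol(x$rotation), x$n_selected))
  k <- min(4L, length(x$var_pct))
  cat("  explained variance:",
      paste(sprintf("%.2f%%", x$var_pct[1:k]), collapse = ", "),
      if (length(x$var_pct) > k) "..." else "", "\n")
  invisible(x)
}

#' Number of components explaining a cumulative variance threshold
#'
#' @param model an [fit_pca()] model
#' @param threshold_pct cumulative explained-variance threshold in percent
#'   (default 99.99)
#' @return the smallest component count whose cumulative explained variance
#'   reaches the threshold
#' @export
select_components <- function(model, threshold_pct = 99.99) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  cum <- cumsum(model$var_pct)
  # tolerate rounding at the 100% end
  which(cum >= threshold_pct - 1e-9)[1]
}

#' Project spectra into a fitted PCA space
#'
#' Standardizes with the training center/scale, rotates by the loadings and
#' truncates to `n_components`.
#'
#' @param spectra matrix (samples x channels) on the model's channel grid
#' @param model an [fit_pca()] model
#' @param n_components number of leading scores to keep (default: the
#'   model's `n_selected`)
#' @return score matrix, samples x n_components
#' @export
project_pca <- function(spectra, model, n_components = model$n_selected) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != nrow(model$rotation))
    stop("spectra are not on the model's channel grid")
  z <- sweep(sweep(spectra, 2L, model$center), 2L, model$scale, "/")
  (z %*% model$rotation)[, seq_len(n_components), drop = FALSE]
}

#' Reconstruct standardized spectra from scores (all components)
#' @param scores full score matrix
#' @param model an [fit_pca()] model
#' @return standardized data matrix
#' @export
reconstruct_pca <- function(scores, model) {
  scores %*% t(model$rotation[, seq_len(ncol(scores)), drop = FALSE])
}

#' Per-class confidence ellipses in a 2-D score plane
#'
#' Ellipse of the stated normal-theory confidence level from each class's
#' 2-D mean and covariance; the axes lengths are the covariance eigenvalue
#' square roots scaled by the chi-square quantile radius.
#'
#' @param scores_2d two-column score matrix
#' @param labels class labels, one per row
#' @param level confidence level in (0, 1); `level = 0` degenerates to the
#'   class centroid
#' @return data frame per class: center, semi-axis lengths `a >= b`,
#'   orientation (radians), and a `degenerate` flag for singular covariances
#' @export
confidence_ellipse <- function(scores_2d, labels, level = 0.95) {
  stopifnot(ncol(scores_2d) == 2L, level >= 0, level < 1)
  classes <- sort(unique(labels))
  out <- lapply(classes, function(cl) {
    pts <- scores_2d[labels == cl, , drop = FALSE]
    if (nrow(pts) < 3L) stop("need >= 3 points per class: ", cl)
    ctr <- colMeans(pts)
    cv <- stats::cov(pts)
    ev <- eigen(cv, symmetric = TRUE)
    degenerate <- any(ev$values <= .Machine$double.eps * max(ev$values, 1))
    r <- sqrt(stats::qchisq(level, df = 2))
    data.frame(class = cl, cx = ctr[1], cy = ctr[2],
               a = r * sqrt(max(ev$values[1], 0)),
               b = r * sqrt(max(ev$values[2], 0)),
               angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Seeded per-class subsample for exploratory biplots
#'
#' Caps each class at `n_per_class` randomly chosen samples (classes smaller
#' than the cap are kept whole); intended for plotting only — classifier
#' training uses the full library.
#'
#' @param library a [spectral_library()]
#' @param n_per_class cap per class (default 2000)
#' @param seed integer seed
#' @return subsampled [spectral_library()]
#' @export
subsample_per_class <- function(library, n_per_class = 2000, seed = 1) {
  set.seed(as.integer(seed))
  keep <- unlist(lapply(sort(unique(library$labels)), function(cl) {
    idx <- which(library$labels == cl)
    if (length(idx) > n_per_class) sort(sample(idx, n_per_class)) else idx
  }))
  spectral_library(library$spectra[keep, , drop = FALSE],
                   library$labels[keep], library$grid,
                   library$provenance[keep, , drop = FALSE],
                   scheme = library$scheme)
}

#' Serialize / load a PCA model as structured text (YAML)
#' @param model an [fit_pca()] model
#' @param path file path
#' @export
write_pca_model <- function(model, path) {
  yaml::write_yaml(list(center = as.numeric(model$center),
                        scale = as.numeric(model$scale),
                        rotation = as.numeric(model$rotation),
                        n_channels = nrow(model$rotation),
                        sdev = as.numeric(model$sdev),
                        var_pct = as.numeric(model$var_pct),
                        zero_var_channels = as.integer(model$zero_var_channels),
                        n_selected = model$n_selected),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  y <- yaml::read_yaml(path)
  nch <- y$n_channels
  structure(list(center = as.numeric(y$center), scale = as.numeric(y$scale),
                 rotation = matrix(as.numeric(y$rotation), nrow = nch),
                 sdev = as.numeric(y$sdev), var_pct = as.numeric(y$var_pct),
                 zero_var_channels = as.integer(y$zero_var_channels),
                 n_selected = as.integer(y$n_selected)),
            class = "hsi_pca")
}
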