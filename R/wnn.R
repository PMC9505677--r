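## Wide neural network pixel classifier: a single hidden layer of
## rectified-linear units feeding a softmax output, trained by full-batch
## L-BFGS on the multinomial cross-entropy. Inputs are standardized with
## training statistics and, optionally, projected onto the principal
## components explaining a cumulative-variance threshold before training;
## new cubes are pushed through the identical transform at prediction time.

#' Classifier configuration
#'
#' Defaults mirror the reference training setup: a single hidden layer of
#' 100 rectified-linear neurons, no regularization, input standardization
#' on, five-fold cross-validation, and PCA truncation at 99.99% cumulative
#' explained variance.
#'
#' @param hidden_units hidden layer width (>= 1)
#' @param l2 ridge penalty on the weights (0 = none)
#' @param standardize standardize input features with training mean/sd
#' @param cv_folds folds for [cross_validate()] (>= 2)
#' @param use_pca project inputs onto leading principal components
#' @param pca_threshold_pct cumulative-variance threshold for component
#'   selection (percent)
#' @param seed seed for weight initialization and fold assignment
#' @param maxit maximum L-BFGS iterations
#' @param tol relative convergence tolerance passed to the optimizer
#' @return a `wnn_config` list
#' @export
wnn_config <- function(hidden_units = 100, l2 = 0, standardize = TRUE,
                       cv_folds = 5, use_pca = TRUE,
                       pca_threshold_pct = 99.99, seed = 1,
                       maxit = 300, tol = 1e-8) {
  stopifnot(hidden_units >= 1, cv_folds >= 2, l2 >= 0)
  structure(list(hidden_units = as.integer(hidden_units), l2 = l2,
                 standardize = standardize, cv_folds = as.integer(cv_folds),
                 use_pca = use_pca, pca_threshold_pct = pca_threshold_pct,
                 seed = as.integer(seed), maxit = as.integer(maxit),
                 tol = tol),
            class = "wnn_config")
}

# ---- network internals ------------------------------------------------------

wnn_unpack <- function(theta, d, h, k) {
  n1 <- (d + 1L) * h
  list(W1 = matrix(theta[seq_len(n1)], d + 1L, h),
       W2 = matrix(theta[-seq_len(n1)], h + 1L, k))
}

# loss and analytic gradient of softmax cross-entropy through one ReLU layer
wnn_objective <- function(theta, X1, Yind, d, h, k, l2) {
  w <- wnn_unpack(theta, d, h, k)
  n <- nrow(X1)
  A <- X1 %*% w$W1                       # n x h
  H <- pmax(A, 0)
  H1 <- cbind(1, H)
  Z <- H1 %*% w$W2                       # n x k
  Z <- Z - apply(Z, 1L, max)
  expZ <- exp(Z)
  P <- expZ / rowSums(expZ)
  loss <- -sum(log(pmax(P[Yind], 1e-300))) / n +
    l2 / 2 * (sum(w$W1[-1, ]^2) + sum(w$W2[-1, ]^2))
  dZ <- P
  dZ[Yind] <- dZ[Yind] - 1
  dZ <- dZ / n
  gW2 <- crossprod(H1, dZ)
  dH <- dZ %*% t(w$W2[-1, , drop = FALSE])
  dA <- dH * (A > 0)
  gW1 <- crossprod(X1, dA)
  if (l2 > 0) {
    gW1[-1, ] <- gW1[-1, ] + l2 * w$W1[-1, ]
    gW2[-1, ] <- gW2[-1, ] + l2 * w$W2[-1, ]
  }
  list(loss = loss, grad = c(gW1, gW2))
}

wnn_fit_core <- function(X, y_factor, config) {
  d <- ncol(X); k <- nlevels(y_factor); h <- config$hidden_units
  n <- nrow(X)
  X1 <- cbind(1, X)
  Yind <- cbind(seq_len(n), as.integer(y_factor))
  set.seed(config$seed)
  theta0 <- c(matrix(stats::rnorm((d + 1L) * h, 0, sqrt(2 / (d + 1L))),
                     d + 1L, h),
              matrix(stats::rnorm((h + 1L) * k, 0, sqrt(2 / (h + 1L))),
                     h + 1L, k))
  fn <- function(th) wnn_objective(th, X1, Yind, d, h, k, config$l2)$loss
  gr <- function(th) wnn_objective(th, X1, Yind, d, h, k, config$l2)$grad
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$maxit,
                                     factr = config$tol / .Machine$double.eps))
  wnn_unpack(opt$par, d, h, k)
}

wnn_forward_scores <- function(weights, X) {
  A <- cbind(1, X) %*% weights$W1
  Z <- cbind(1, pmax(A, 0)) %*% weights$W2
  Z <- Z - apply(Z, 1L, max)
  expZ <- exp(Z)
  expZ / rowSums(expZ)
}

# feature pipeline: standardize -> optional PCA truncation
wnn_features <- function(spectra, transform) {
  x <- as.matrix(spectra)
  if (!is.null(transform$pca))
    return(project_pca(x, transform$pca, transform$pca$n_selected))
  if (!is.null(transform$center))
    x <- sweep(sweep(x, 2L, transform$center), 2L, transform$scale, "/")
  x
}

# ---- user-facing training / prediction -------------------------------------

#' Train the wide neural network on a spectral library
#'
#' Deterministic for a given seed and data. When `config$use_pca` is on, a
#' standardized PCA is fitted to the library and inputs are truncated to the
#' components explaining `config$pca_threshold_pct` of the variance; the PCA
#' transform is stored with the model so new cubes are projected into the
#' same space before classification. Cross-validated accuracy (see
#' [cross_validate()]) is recorded in the model metadata when
#' `record_cv = TRUE`.
#'
#' @param library a [spectral_library()] (or a list with `spectra`, `labels`)
#' @param config a [wnn_config()]
#' @param record_cv also run k-fold cross-validation and store the accuracy
#' @return object of class `wnn_model`
#' @export
train_wnn <- function(library, config = wnn_config(), record_cv = FALSE) {
  x <- as.matrix(library$spectra)
  y <- as.character(library$labels)
  if (any(!is.finite(x))) stop("training spectra contain non-finite entries")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes to train")
  yf <- factor(y, levels = classes)

  transform <- list(center = NULL, scale = NULL, pca = NULL)
  if (config$use_pca) {
    pca <- fit_pca(x)
    pca$n_selected <- select_components(pca, config$pca_threshold_pct)
    transform$pca <- pca
  } else if (config$standardize) {
    transform$center <- colMeans(x)
    s <- apply(x, 2L, stats::sd); s[s == 0] <- 1
    transform$scale <- s
  }
  feats <- wnn_features(x, transform)
  weights <- wnn_fit_core(feats, yf, config)
  cv_acc <- if (record_cv) cross_validate(library, config) else NA_real_
  train_pred <- classes[max.col(wnn_forward_scores(weights, feats),
                                ties.method = "first")]
  structure(list(weights = weights, classes = classes,
                 transform = transform, config = config,
                 grid = library$grid,
                 train_accuracy = mean(train_pred == y),
                 cv_accuracy = cv_acc),
            class = "wnn_model")
}

#' @export
print.wnn_model <- function(x, ...) {
  nfeat <- nrow(x$weights$W1) - 1L
  cat(sprintf("<wnn_model> %d features -> %d ReLU units -> %d classes\n",
              nfeat, ncol(x$weights$W1), length(x$classes)))
  cat(sprintf("  training accuracy %.1f%%", 100 * x$train_accuracy))
  if (!is.na(x$cv_accuracy))
    cat(sprintf(", %d-fold CV accuracy %.1f%%", x$config$cv_folds,
                100 * x$cv_accuracy))
  cat("\n")
  invisible(x)
}

#' Predict classes for a matrix of spectra
#'
#' @param object a [train_wnn()] model
#' @param newdata matrix of spectra (samples x channels, on the training
#'   grid)
#' @param type `"class"` for hard labels (ties broken toward the lowest
#'   class index) or `"score"` for the softmax score matrix
#' @param ... unused
#' @return character vector of class names, or a score matrix
#' @export
predict.wnn_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  feats <- wnn_features(newdata, object$transform)
  scores <- wnn_forward_scores(object$weights, feats)
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified per class with seeded assignment, so per-class fold
#' sizes differ by at most one; the estimate is the pooled held-out accuracy.
#'
#' @param library a [spectral_library()]
#' @param config a [wnn_config()]
#' @return mean held-out accuracy in `[0, 1]`, with per-fold accuracies as
#'   attribute `folds`
#' @export
cross_validate <- function(library, config = wnn_config()) {
  x <- as.matrix(library$spectra)
  y <- as.character(library$labels)
  classes <- sort(unique(y))
  k <- config$cv_folds
  small <- names(which(table(y) < k))
  if (length(small))
    stop("class(es) smaller than fold count: ", paste(small, collapse = ", "))
  set.seed(config$seed)
  fold <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    sub <- spectral_library(x[tr, , drop = FALSE], y[tr], library$grid,
                            library$provenance[tr, , drop = FALSE],
                            scheme = library$scheme)
    m <- train_wnn(sub, config, record_cv = FALSE)
    pred <- predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  acc <- correct / length(y)
  attr(acc, "folds") <- k
  acc
}

#' Classify every pixel of a calibrated cube
#'
#' Applies the classifier independently per pixel (no spatial context).
#' Pixels with any invalid channel — from the cube's validity mask or an
#' explicit `mask` argument — receive the invalid code 0.
#'
#' @param refl_cube calibrated reflectance [hypercube()] on the model's
#'   training grid
#' @param model a [train_wnn()] model
#' @param mask optional logical `rows x cols` matrix of pixels to classify
#' @return a `prediction_map`: [label_map()] of predicted classes (codes in
#'   the model's class order) plus the per-pixel score matrix
#' @export
predict_cube <- function(refl_cube, model, mask = NULL) {
  if (refl_cube$kind != "reflectance")
    stop("classification requires a calibrated (reflectance) cube")
  if (!grids_identical(refl_cube$grid, model$grid))
    stop("cube grid does not match the model's training grid")
  d <- dim(refl_cube$data)
  X <- cube_pixel_matrix(refl_cube)
  valid <- rowSums(!is.finite(X)) == 0L
  if (!is.null(refl_cube$mask)) {
    m <- matrix(aperm(refl_cube$mask, c(2L, 1L, 3L)), nrow = d[1] * d[2])
    valid <- valid & rowSums(!m) == 0L
  }
  if (!is.null(mask)) valid <- valid & as.vector(t(mask))
  codes <- integer(d[1] * d[2])                 # 0 = invalid
  scores <- NULL
  if (any(valid)) {
    sc <- predict(model, X[valid, , drop = FALSE], type = "score")
    codes[valid] <- max.col(sc, ties.method = "first")
    scores <- sc
  }
  labels <- matrix(codes, d[1], d[2], byrow = TRUE)
  legend <- stats::setNames(model$classes,
                            as.character(seq_along(model$classes)))
  structure(list(labels = label_map(labels, legend),
                 classes = model$classes, valid = matrix(valid, d[1], d[2],
                                                         byrow = TRUE),
                 scores = scores),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %d x %d px, %d classes, %.2f%% valid\n",
              nrow(x$labels$labels), ncol(x$labels$labels),
              length(x$classes), 100 * mean(x$valid)))
  invisible(x)
}

#' Serialize / load a trained classifier (structured text)
#' @param model a [train_wnn()] model
#' @param path file path (YAML)
#' @export
write_wnn_model <- function(model, path) {
  tr <- model$transform
  yaml::write_yaml(list(
    classes = model$classes,
    W1 = as.numeric(model$weights$W1), d1 = dim(model$weights$W1),
    W2 = as.numeric(model$weights$W2), d2 = dim(model$weights$W2),
    center = if (is.null(tr$center)) NULL else as.numeric(tr$center),
    scale = if (is.null(tr$scale)) NULL else as.numeric(tr$scale),
    has_pca = !is.null(tr$pca),
    pca = if (is.null(tr$pca)) NULL else list(
      center = as.numeric(tr$pca$center), scale = as.numeric(tr$pca$scale),
      rotation = as.numeric(tr$pca$rotation),
      n_channels = nrow(tr$pca$rotation),
      sdev = as.numeric(tr$pca$sdev), var_pct = as.numeric(tr$pca$var_pct),
      n_selected = tr$pca$n_selected),
    grid = list(start = model$grid$start_nm, stop = model$grid$stop_nm,
                step = model$grid$step_nm),
    config = unclass(model$config),
    train_accuracy = model$train_accuracy,
    cv_accuracy = as.numeric(model$cv_accuracy)), path, precision = 17)
  invisible(path)
}

#' @rdname write_wnn_model
#' @export
read_wnn_model <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- list(center = if (is.null(y$center)) NULL else as.numeric(y$center),
             scale = if (is.null(y$scale)) NULL else as.numeric(y$scale),
             pca = NULL)
  if (isTRUE(y$has_pca)) {
    p <- y$pca
    tr$pca <- structure(list(center = as.numeric(p$center),
                             scale = as.numeric(p$scale),
                             rotation = matrix(as.numeric(p$rotation),
                                               nrow = p$n_channels),
                             sdev = as.numeric(p$sdev),
                             var_pct = as.numeric(p$var_pct),
                             zero_var_channels = integer(0),
                             n_selected = as.integer(p$n_selected)),
                        class = "hsi_pca")
  }
  structure(list(
    weights = list(W1 = matrix(as.numeric(y$W1), y$d1[1], y$d1[2]),
                   W2 = matrix(as.numeric(y$W2), y$d2[1], y$d2[2])),
    classes = unlist(y$classes), transform = tr,
    config = do.call(wnn_config, y$config[c("hidden_units", "l2",
                                            "standardize", "cv_folds",
                                            "use_pca", "pca_threshold_pct",
                                            "seed", "maxit", "tol")]),
    grid = build_wavelength_grid(y$grid$start, y$grid$stop, y$grid$step),
    train_accuracy = y$train_accuracy,
    cv_accuracy = y$cv_accuracy),
    class = "wnn_model")
}
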