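test_that("well-separated classes are learned almost perfectly", {
  lib <- blob_library(n_per_class = 60, k = 3, sep = 6, noise_sd = 0.3)
  m <- train_wnn(lib, quick_wnn(use_pca = FALSE))
  expect_gte(m$train_accuracy, 0.99)
  pred <- predict(m, lib$spectra)
  expect_gte(mean(pred == lib$labels), 0.99)
})

test_that("training is deterministic for a fixed seed", {
  lib <- blob_library()
  m1 <- train_wnn(lib, quick_wnn(seed = 5))
  m2 <- train_wnn(lib, quick_wnn(seed = 5))
  expect_identical(m1$weights$W1, m2$weights$W1)
  expect_identical(m1$weights$W2, m2$weights$W2)
  m3 <- train_wnn(lib, quick_wnn(seed = 6))
  expect_false(identical(m1$weights$W1, m3$weights$W1))
})

test_that("training rejects degenerate libraries", {
  grid <- build_wavelength_grid(420, 430, 5)
  one <- spectral_library(matrix(runif(30), 10), rep("a", 10), grid)
  expect_error(train_wnn(one, quick_wnn()), "two classes")
  bad <- spectral_library(matrix(c(NA, runif(29)), 10), rep(c("a", "b"), 5),
                          grid)
  expect_error(train_wnn(bad, quick_wnn()), "non-finite")
})

test_that("cross-validation is stratified with near-equal folds", {
  lib <- blob_library(n_per_class = 52, k = 2)
  acc <- cross_validate(lib, quick_wnn(cv_folds = 5))
  expect_gte(acc, 0.98)                       # separable data
  # fold sizes per class differ by at most one (52 = 5*10 + 2)
  set.seed(quick_wnn()$seed)
  y <- lib$labels
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(1:5, length(idx)))
  }
  for (cl in unique(y)) {
    sizes <- table(fold[y == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  small <- spectral_library(matrix(runif(12), 4), c("a", "a", "b", "b"),
                            build_wavelength_grid(420, 430, 5))
  expect_error(cross_validate(small, quick_wnn(cv_folds = 5)),
               "smaller than fold count")
})

test_that("cross-validated accuracy on permuted labels sits at chance", {
  set.seed(55)
  lib <- blob_library(n_per_class = 60, k = 3, sep = 6)
  lib$labels <- sample(lib$labels)            # break the signal
  acc <- cross_validate(lib, quick_wnn(cv_folds = 5, maxit = 80))
  expect_lt(abs(acc - 1 / 3), 0.13)
})

test_that("pixels equal to class means are classified as their class", {
  grid <- build_wavelength_grid(420, 730, 5)
  idx <- match(grid$centers, FINE_GRID_NM)
  classes <- c("green_algae", "red_algae", "mussel", "panel_white")
  means <- t(vapply(classes, function(cl)
    generate_endmember(cl)$reflectance[idx], numeric(63)))
  set.seed(56)
  spectra <- do.call(rbind, lapply(1:4, function(i)
    means[rep(i, 80), ] * exp(rnorm(80, 0, 0.05))))
  lib <- spectral_library(spectra, rep(classes, each = 80), grid)
  model <- train_wnn(lib, quick_wnn())
  # a cube whose pixels are exactly the class means
  arr <- array(0, c(2, 2, 63))
  arr[1, 1, ] <- means[1, ]; arr[1, 2, ] <- means[2, ]
  arr[2, 1, ] <- means[3, ]; arr[2, 2, ] <- means[4, ]
  cube <- hypercube(arr, grid, kind = "reflectance")
  pred <- predict_cube(cube, model)
  got <- label_classes(pred$labels)[pred$labels$labels]
  expect_equal(as.vector(t(matrix(got, 2, 2))),
               c(classes[1], classes[2], classes[3], classes[4]))
})

test_that("prediction commutes with spatial permutations of pixels", {
  lib <- blob_library(n_per_class = 50, k = 3, n_channels = 12)
  model <- train_wnn(lib, quick_wnn(use_pca = FALSE))
  set.seed(57)
  arr <- array(rnorm(6 * 5 * 12), c(6, 5, 12))
  cube <- hypercube(abs(arr), lib$grid, kind = "reflectance")
  p1 <- predict_cube(cube, model)
  # permute pixels, classify, un-permute
  perm <- sample(30)
  m <- hsifoul:::cube_pixel_matrix(cube)
  cube2 <- hypercube(hsifoul:::pixel_matrix_to_array(m[perm, ], 6, 5),
                     lib$grid, kind = "reflectance")
  p2 <- predict_cube(cube2, model)
  codes1 <- as.vector(t(p1$labels$labels))
  codes2 <- as.vector(t(p2$labels$labels))
  expect_identical(codes2, codes1[perm])
})

test_that("masked pixels receive the invalid code", {
  lib <- blob_library(n_per_class = 40, k = 2, n_channels = 12)
  model <- train_wnn(lib, quick_wnn(use_pca = FALSE))
  arr <- abs(array(rnorm(4 * 4 * 12), c(4, 4, 12)))
  cube <- hypercube(arr, lib$grid, kind = "reflectance")
  all_masked <- predict_cube(cube, model, mask = matrix(FALSE, 4, 4))
  expect_true(all(all_masked$labels$labels == 0L))
  half <- matrix(c(TRUE, FALSE), 4, 4)
  p <- predict_cube(cube, model, mask = half)
  expect_true(all((p$labels$labels == 0L) == !half))
})

test_that("score ties break toward the lowest class index", {
  grid <- build_wavelength_grid(420, 430, 5)
  model <- structure(list(
    weights = list(W1 = matrix(0, 4, 3), W2 = matrix(0, 4, 2)),
    classes = c("a", "b"),
    transform = list(center = rep(0, 3), scale = rep(1, 3), pca = NULL),
    config = wnn_config(), grid = grid,
    train_accuracy = NA_real_, cv_accuracy = NA_real_),
    class = "wnn_model")
  pred <- predict(model, matrix(runif(9), 3))
  expect_true(all(pred == "a"))
})

test_that("PCA at full variance agrees with raw-feature training", {
  lib <- blob_library(n_per_class = 50, k = 3, sep = 8, noise_sd = 0.2)
  m_raw <- train_wnn(lib, quick_wnn(use_pca = FALSE, seed = 3))
  m_pca <- train_wnn(lib, quick_wnn(use_pca = TRUE,
                                    pca_threshold_pct = 100, seed = 3))
  set.seed(58)
  probe <- lib$spectra + matrix(rnorm(length(lib$spectra), 0, 0.05),
                                nrow(lib$spectra))
  expect_identical(predict(m_raw, probe), predict(m_pca, probe))
})

test_that("grid mismatches are rejected at prediction time", {
  lib <- blob_library(n_per_class = 40, k = 2, n_channels = 12)
  model <- train_wnn(lib, quick_wnn(use_pca = FALSE))
  other <- hypercube(abs(array(rnorm(4 * 4 * 10), c(4, 4, 10))),
                     build_wavelength_grid(420, 465, 5),
                     kind = "reflectance")
  expect_error(predict_cube(other, model), "grid")
})

test_that("trained models round trip through serialization", {
  lib <- blob_library(n_per_class = 40, k = 3, n_channels = 10)
  model <- train_wnn(lib, quick_wnn(use_pca = TRUE))
  path <- file.path(withr::local_tempdir(), "model.yaml")
  write_wnn_model(model, path)
  back <- read_wnn_model(path)
  set.seed(59)
  probe <- abs(matrix(rnorm(200), 20, 10))
  expect_identical(predict(back, probe), predict(model, probe))
  expect_equal(predict(back, probe, type = "score"),
               predict(model, probe, type = "score"), tolerance = 1e-10)
})
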