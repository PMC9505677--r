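## End-to-end orchestration: simulate -> calibrate -> library -> pca ->
## train -> classify -> evaluate, from one declarative configuration with a
## single global seed fanned out into per-stage substreams.

pipeline_config_keys <- c(
  "seed", "rows", "cols", "grid", "background", "classes", "scheme",
  "noise", "scene_jitter_sd", "specimen_brightness_sd", "specimen_dip_sd",
  "d_w", "r_ref", "target_fill", "sg_order", "sg_window",
  "epsilon", "wnn", "record_cv", "test_coverage_target")

wnn_config_keys <- c("hidden_units", "l2", "standardize", "cv_folds",
                     "use_pca", "pca_threshold_pct", "seed", "maxit", "tol")

#' Declarative configuration for a full simulated pipeline run
#'
#' The defaults describe the packaged demo: a 120 x 160 pixel frame scanned
#' over 420--730 nm in 5 nm steps (63 channels), a white-panel background
#' bearing green/red/brown algae, mussel and barnacle patches, realistic
#' noise, a 10% reference standard, Savitzky-Golay smoothing (order 2,
#' 9 channels), PCA truncation at 99.99% variance, and the 100-unit
#' rectified-linear network.
#'
#' @param seed global seed; all stage randomness derives from it
#' @param rows,cols frame size
#' @param grid list with `start`, `stop`, `step` (nm)
#' @param background panel class used as scene background
#' @param classes biofouling classes placed on the panels
#' @param scheme `"coarse"` or `"fine"` annotation scheme
#' @param noise simulate sensor noise
#' @param scene_jitter_sd per-pixel brightness jitter (log-scale s.d.)
#' @param specimen_brightness_sd,specimen_dip_sd endmember realization
#'   jitter; the test target's specimens are drawn independently of the
#'   training specimens
#' @param d_w one-way water path (m)
#' @param r_ref reference-standard reflectance
#' @param target_fill exposure-planning fill fraction
#' @param sg_order,sg_window Savitzky-Golay parameters
#' @param epsilon calibration denominator guard (counts)
#' @param wnn list of [wnn_config()] overrides
#' @param record_cv run cross-validation during training
#' @param test_coverage_target approximate per-class coverage fraction of the
#'   test target's fouling patches
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1, rows = 120, cols = 160,
                            grid = list(start = 420, stop = 730, step = 5),
                            background = "panel_white",
                            classes = c("green_algae", "red_algae",
                                        "brown_algae", "mussel", "barnacle"),
                            scheme = "coarse",
                            noise = TRUE,
                            scene_jitter_sd = 0.08,
                            specimen_brightness_sd = 0.05,
                            specimen_dip_sd = 0.10,
                            d_w = 0.4, r_ref = 0.10, target_fill = 0.8,
                            sg_order = 2, sg_window = 9,
                            epsilon = 10,
                            wnn = list(), record_cv = FALSE,
                            test_coverage_target = 0.10) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(pipeline_config_keys, names(cfg))
  if (length(missing))
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  unknown_wnn <- setdiff(names(cfg$wnn), wnn_config_keys)
  if (length(unknown_wnn))
    stop("unknown wnn key(s): ", paste(unknown_wnn, collapse = ", "))
  stopifnot(cfg$rows > 0, cfg$cols > 0, cfg$r_ref > 0, cfg$r_ref <= 1)
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()]
#' @return validated `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# deterministic fan-out of the global seed into independent stage seeds
stage_seeds <- function(seed, n = 8L) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# training layout: a band of clear panel on top (panel ROIs live there), then
# one rectangular patch per class arranged on a grid
training_layout <- function(cfg) {
  n <- length(cfg$classes)
  band <- max(8L, round(cfg$rows * 0.18))
  ncell <- ceiling(sqrt(n))
  nrowc <- ceiling(n / ncell)
  ch <- (cfg$rows - band) %/% nrowc
  cw <- cfg$cols %/% ncell
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- (i - 1L) %/% ncell; ci <- (i - 1L) %% ncell
    r0 <- band + ri * ch; c0 <- ci * cw
    m <- max(2L, round(min(ch, cw) * 0.12))
    shapes[[i]] <- list(type = "rect", class = cfg$classes[i],
                        r0 = r0 + m, r1 = r0 + ch - m,
                        c0 = c0 + m, c1 = c0 + cw - m)
  }
  shapes
}

training_rois <- function(cfg, layout, cube_id = "train") {
  recs <- lapply(layout, function(s)
    data.frame(label = s$class, r0 = s$r0 + 1L, r1 = s$r1 - 1L,
               c0 = s$c0 + 1L, c1 = s$c1 - 1L, stringsAsFactors = FALSE))
  band <- max(8L, round(cfg$rows * 0.18))
  panel_label <- if (cfg$scheme == "coarse") "panel" else cfg$background
  recs[[length(recs) + 1L]] <- data.frame(
    label = panel_label, r0 = 2L, r1 = band - 2L,
    c0 = 2L, c1 = cfg$cols - 2L, stringsAsFactors = FALSE)
  roi_set(do.call(rbind, recs), cube_id = cube_id)
}

# test layout: one ellipse per class at deterministic positions
test_layout <- function(cfg) {
  n <- length(cfg$classes)
  frac <- cfg$test_coverage_target
  area <- frac * cfg$rows * cfg$cols
  rr <- sqrt(area / pi) * sqrt(cfg$rows / cfg$cols)
  rc <- sqrt(area / pi) * sqrt(cfg$cols / cfg$rows)
  ncell <- ceiling(sqrt(n)); nrowc <- ceiling(n / ncell)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- (i - 1L) %/% ncell; ci <- (i - 1L) %% ncell
    ctr <- c((ri + 0.5) / nrowc * cfg$rows, (ci + 0.5) / ncell * cfg$cols)
    shapes[[i]] <- list(type = "ellipse", class = cfg$classes[i],
                        center = ctr, radii = c(rr, rc))
  }
  shapes
}

#' Run the full simulated pipeline
#'
#' Simulates spatially disjoint training and test acquisitions (scene,
#' bright-field and dark-field cubes each), calibrates and smooths them,
#' assembles the annotated library from the training cube, trains the
#' classifier, segments the test cube and reports confusion metrics and
#' per-class coverage against the exact simulated ground truth. With noise
#' and jitter off the run is bit-reproducible.
#'
#' @param config a [pipeline_config()] (or a YAML path)
#' @param out_dir optional directory for artifacts (ENVI cubes, label
#'   rasters, library CSV, model, reports, provenance record)
#' @return a `pipeline_run` list: `library`, `model`, `prediction`,
#'   `confusion`, `metrics`, `coverage`, `ground_truth_coverage`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  cfg <- config
  ss <- stage_seeds(cfg$seed)

  grid <- build_wavelength_grid(cfg$grid$start, cfg$grid$stop, cfg$grid$step)
  all_classes <- unique(c(cfg$background, cfg$classes))

  em_train <- generate_endmember_set(
    all_classes, seed = ss[1],
    brightness_jitter_sd = cfg$specimen_brightness_sd,
    dip_jitter_sd = cfg$specimen_dip_sd)
  em_test <- generate_endmember_set(
    all_classes, seed = ss[2],
    brightness_jitter_sd = cfg$specimen_brightness_sd,
    dip_jitter_sd = cfg$specimen_dip_sd)

  instrument <- instrument_model(cfg$rows, cfg$cols, grid = grid,
                                 water = water_model(d_w = cfg$d_w))
  max_refl <- max(vapply(em_train, function(e) max(e$reflectance), 0),
                  vapply(em_test, function(e) max(e$reflectance), 0))
  headroom <- if (cfg$scene_jitter_sd > 0) exp(3.5 * cfg$scene_jitter_sd) else 1
  plan <- plan_exposures(instrument,
                         reference_reflectance = min(1.2, max_refl * headroom),
                         target_fill = cfg$target_fill)

  scn_train <- generate_scene(training_layout(cfg), cfg$rows, cfg$cols,
                              em_train, background = cfg$background,
                              brightness_jitter_sd = cfg$scene_jitter_sd,
                              seed = ss[3])
  scn_test <- generate_scene(test_layout(cfg), cfg$rows, cfg$cols,
                             em_test, background = cfg$background,
                             brightness_jitter_sd = cfg$scene_jitter_sd,
                             seed = ss[4])

  acq_train <- simulate_acquisition(scn_train, instrument, plan,
                                    ref_reflectance = cfg$r_ref,
                                    noise = cfg$noise, seed = ss[5])
  acq_test <- simulate_acquisition(scn_test, instrument, plan,
                                   ref_reflectance = cfg$r_ref,
                                   noise = cfg$noise, seed = ss[6])

  calibrate_one <- function(acq) {
    cs <- calibration_set(acq$scene, acq$bright, acq$dark, r_ref = cfg$r_ref)
    smooth_spectra(reflectance_transform(cs, epsilon = cfg$epsilon),
                   poly_order = cfg$sg_order,
                   window_channels = cfg$sg_window)
  }
  refl_train <- calibrate_one(acq_train)
  refl_test <- calibrate_one(acq_test)

  rois <- training_rois(cfg, training_layout(cfg))
  lib <- annotate(refl_train, rois,
                  scheme = if (cfg$scheme == "fine") "fine" else "coarse")

  wnn_args <- utils::modifyList(list(seed = ss[7]), cfg$wnn)
  wcfg <- do.call(wnn_config, wnn_args)
  model <- train_wnn(lib, wcfg, record_cv = cfg$record_cv)

  pred <- predict_cube(refl_test, model)

  # ground truth relabeled to the scheme actually trained
  truth <- scn_test$labels
  if (cfg$scheme == "coarse") {
    mapping <- default_class_mapping()
    legend <- stats::setNames(unname(mapping[label_classes(truth)]),
                              names(truth$legend))
    truth <- label_map(truth$labels, legend)
  }
  cm <- confusion(truth, pred)
  metrics <- class_metrics(cm)
  cov <- coverage(pred)

  run <- structure(list(
    config = cfg, grid = grid, instrument = instrument, plan = plan,
    scene_train = scn_train, scene_test = scn_test,
    refl_train = refl_train, refl_test = refl_test,
    library = lib, pca = model$transform$pca, model = model,
    prediction = pred, confusion = cm, metrics = metrics, coverage = cov,
    ground_truth_coverage = ground_truth_coverage(scn_test)),
    class = "pipeline_run")

  if (!is.null(out_dir)) write_pipeline_artifacts(run, acq_test, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  library: %d samples, %d classes (%s scheme)\n",
              nrow(x$library$spectra), length(unique(x$library$labels)),
              x$config$scheme))
  if (!is.null(x$pca))
    cat(sprintf("  pca: %d of %d components selected\n",
                x$pca$n_selected, ncol(x$pca$rotation)))
  cat(sprintf("  overall test accuracy: %.2f%%\n",
              x$metrics$overall_accuracy_pct))
  cat("  coverage (predicted | truth):\n")
  gt <- x$ground_truth_coverage
  if (x$config$scheme == "coarse")
    names(gt) <- unname(default_class_mapping()[names(gt)])
  for (cl in x$coverage$classes)
    cat(sprintf("    %-16s %6.2f%% | %6.2f%%\n", cl,
                x$coverage$coverage_pct[[cl]],
                if (cl %in% names(gt)) gt[[cl]] else 0))
  invisible(x)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

write_pipeline_artifacts <- function(run, acq_test, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_hypercube(acq_test$scene, p("test_raw.bsq"))
  write_hypercube(run$refl_test, p("test_reflectance.bsq"))
  write_label_map(run$scene_test$labels, p("test_ground_truth.lbl"))
  write_label_map(run$prediction$labels, p("test_prediction.lbl"))
  write_library(run$library, p("library.csv"))
  write_wnn_model(run$model, p("model.yaml"))
  write_report(run$metrics, run$coverage, p("report.yaml"))
  yaml::write_yaml(list(seed = run$config$seed,
                        config_hash = config_hash(run$config),
                        config = unclass(run$config),
                        timestamp = format(Sys.time(), tz = "UTC")),
                   p("provenance.yaml"))
  invisible(out_dir)
}
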