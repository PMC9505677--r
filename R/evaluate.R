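## Confusion-matrix metrics against ground truth and per-class coverage.

#' Confusion matrix of a prediction against ground truth
#'
#' Rows are ground truth, columns predictions. Pixels invalid in either map
#' (code 0) are excluded from the counts.
#'
#' @param truth a [label_map()] ground truth
#' @param pred a `prediction_map` from [predict_cube()] or a [label_map()]
#' @param classes common class list; default: union of both legends in truth
#'   legend order
#' @return object of class `confusion_matrix`: integer `counts` (K x K),
#'   `classes`, `n_invalid`
#' @export
confusion <- function(truth, pred, classes = NULL) {
  pred_lm <- if (inherits(pred, "prediction_map")) pred$labels else pred
  if (!identical(dim(truth$labels), dim(pred_lm$labels)))
    stop("truth and prediction dimensions differ")
  tnames <- label_classes(truth); pnames <- label_classes(pred_lm)
  if (is.null(classes)) classes <- union(tnames, pnames)
  if (!all(tnames %in% classes) || !all(pnames %in% classes))
    stop("label outside the shared class list")
  t_name <- c("", tnames)[truth$labels + 1L]
  p_name <- c("", pnames)[pred_lm$labels + 1L]
  keep <- t_name != "" & p_name != ""
  tf <- factor(t_name[keep], levels = classes)
  pf <- factor(p_name[keep], levels = classes)
  counts <- table(truth = tf, prediction = pf)
  structure(list(counts = unclass(counts), classes = classes,
                 n_invalid = sum(!keep)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d pixels (%d excluded)\n",
              length(x$classes), sum(x$counts), x$n_invalid))
  print(x$counts)
  invisible(x)
}

#' Per-class and overall metrics from a confusion matrix
#'
#' Overall accuracy is the matrix trace over its total. Per class, the true
#' positive rate (recall) is the diagonal element over the row sum and the
#' positive predictive value (precision) the diagonal element over the
#' column sum; miss and false-discovery rates are their complements, so
#' TPR + FNR = 100 and PPV + FDR = 100 exactly. A class absent from the
#' ground truth (empty row) has undefined TPR/FNR; absent from the
#' predictions (empty column), undefined PPV/FDR — both reported as `NA`
#' with the `undefined` columns flagging them.
#'
#' @param cm a [confusion()] matrix
#' @return object of class `class_metrics`: `overall_accuracy_pct` and a
#'   per-class data frame with `tpr_pct`, `fnr_pct`, `ppv_pct`, `fdr_pct`
#' @export
class_metrics <- function(cm) {
  m <- cm$counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  diag_v <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  tpr <- ifelse(rs > 0, 100 * diag_v / rs, NA_real_)
  ppv <- ifelse(cs > 0, 100 * diag_v / cs, NA_real_)
  per_class <- data.frame(
    class = cm$classes,
    tpr_pct = tpr, fnr_pct = 100 - tpr,
    ppv_pct = ppv, fdr_pct = 100 - ppv,
    tpr_undefined = rs == 0, ppv_undefined = cs == 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(overall_accuracy_pct = 100 * sum(diag_v) / total,
                 per_class = per_class, total = total),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> overall accuracy %.2f%% (n = %d)\n",
              x$overall_accuracy_pct, x$total))
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-16s TPR %6s  PPV %6s\n", df$class[i],
                ifelse(is.na(df$tpr_pct[i]), "--",
                       sprintf("%.2f", df$tpr_pct[i])),
                ifelse(is.na(df$ppv_pct[i]), "--",
                       sprintf("%.2f", df$ppv_pct[i]))))
  invisible(x)
}

#' Per-class coverage of a segmented panel
#'
#' Coverage is the ratio between the pixels assigned to each class and the
#' total number of valid pixels; percentages sum to 100. Per-class binary
#' masks are returned for coverage-map rendering.
#'
#' @param pred a `prediction_map` or [label_map()]
#' @return object of class `coverage_report`: per-class `pixels` and
#'   `coverage_pct`, `total_valid`, and `masks` (list of logical matrices)
#' @export
coverage <- function(pred) {
  lm <- if (inherits(pred, "prediction_map")) pred$labels else pred
  classes <- label_classes(lm)
  valid <- lm$labels != 0L
  total <- sum(valid)
  if (total == 0) stop("all pixels invalid")
  counts <- tabulate(lm$labels[valid], nbins = length(classes))
  masks <- lapply(seq_along(classes), function(k) lm$labels == k)
  names(masks) <- classes
  structure(list(classes = classes,
                 pixels = stats::setNames(counts, classes),
                 coverage_pct = stats::setNames(100 * counts / total, classes),
                 total_valid = total, masks = masks),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d valid pixels\n", x$total_valid))
  for (i in seq_along(x$classes))
    cat(sprintf("  %-16s %8d px  %6.2f%%\n", x$classes[i], x$pixels[i],
                x$coverage_pct[i]))
  invisible(x)
}

#' Write an evaluation report as structured text
#' @param metrics a [class_metrics()] object (or `NULL`)
#' @param cov a [coverage()] report (or `NULL`)
#' @param path file path
#' @export
write_report <- function(metrics, cov, path) {
  out <- list()
  if (!is.null(metrics))
    out$metrics <- list(
      overall_accuracy_pct = round(metrics$overall_accuracy_pct, 2),
      per_class = lapply(seq_len(nrow(metrics$per_class)), function(i) {
        r <- metrics$per_class[i, ]
        list(class = r$class, tpr_pct = round(r$tpr_pct, 2),
             fnr_pct = round(r$fnr_pct, 2), ppv_pct = round(r$ppv_pct, 2),
             fdr_pct = round(r$fdr_pct, 2))
      }))
  if (!is.null(cov))
    out$coverage <- list(
      total_valid = cov$total_valid,
      per_class = as.list(round(cov$coverage_pct, 2)))
  yaml::write_yaml(out, path)
  invisible(path)
}
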