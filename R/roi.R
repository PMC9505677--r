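#' Construct a set of rectangular regions of interest
#'
#' ROIs delimit annotated regions on a cube from which labeled pixel spectra
#' are harvested for the spectral library. Rectangles use 0-based, half-open
#' bounds `[r0, r1) x [c0, c1)` so that the pixel count is exactly
#' `(r1 - r0) * (c1 - c0)`.
#'
#' @param rois data frame with columns `label`, `r0`, `r1`, `c0`, `c1` and
#'   optionally `cube_id`
#' @param cube_id default cube identifier applied where the column is absent
#' @return object of class `roi_set` (a validated data frame)
#' @export
roi_set <- function(rois, cube_id = "cube") {
  rois <- as.data.frame(rois, stringsAsFactors = FALSE)
  need <- c("label", "r0", "r1", "c0", "c1")
  if (!all(need %in% names(rois)))
    stop("roi table needs columns: ", paste(need, collapse = ", "))
  if (!nrow(rois)) stop("roi set must be non-empty")
  if (is.null(rois$cube_id)) rois$cube_id <- cube_id
  for (k in c("r0", "r1", "c0", "c1")) rois[[k]] <- as.integer(rois[[k]])
  if (any(rois$r1 <= rois$r0) || any(rois$c1 <= rois$c0))
    stop("degenerate rectangle: require r1 > r0 and c1 > c0")
  if (any(rois$r0 < 0L) || any(rois$c0 < 0L))
    stop("rectangle bounds must be nonnegative")
  structure(rois, class = c("roi_set", "data.frame"))
}

#' Read / write ROI sets as structured text
#'
#' One record per line: `label r0 r1 c0 c1 [cube_id]`, whitespace-separated.
#' @param path file path
#' @param rois a [roi_set()]
#' @export
read_roi_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  roi_set(df)
}

#' @rdname read_roi_set
#' @export
write_roi_set <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

check_roi_bounds <- function(roi, rows, cols) {
  if (roi$r1 > rows || roi$c1 > cols)
    stop(sprintf("ROI [%d,%d)x[%d,%d) outside %d x %d image",
                 roi$r0, roi$r1, roi$c0, roi$c1, rows, cols))
}

#' Extract the pixel spectra enclosed by one ROI
#'
#' Pixels are returned in deterministic row-major order (scanning columns
#' within each row of the rectangle).
#'
#' @param cube a [hypercube()]
#' @param roi one-row data frame (or list) with fields `r0`, `r1`, `c0`, `c1`
#' @return list with `coords` (0-based `row`,`col` data frame, one per pixel)
#'   and `spectra` (matrix, pixels x channels)
#' @export
extract_roi_pixels <- function(cube, roi) {
  d <- dim(cube$data)
  check_roi_bounds(roi, d[1], d[2])
  rr <- seq.int(roi$r0, roi$r1 - 1L)
  cc <- seq.int(roi$c0, roi$c1 - 1L)
  coords <- data.frame(row = rep(rr, each = length(cc)),
                       col = rep(cc, times = length(rr)))
  block <- cube$data[rr + 1L, cc + 1L, , drop = FALSE]
  # row-major flatten of the rectangle
  spectra <- matrix(aperm(block, c(2L, 1L, 3L)),
                    nrow = length(rr) * length(cc), ncol = d[3])
  list(coords = coords, spectra = spectra)
}
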