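#' Construct a hypercube
#'
#' A hypercube stacks two spatial dimensions and one spectral dimension: a
#' `rows x cols x channels` array in which every pixel holds a full spectrum.
#' Values are either raw camera counts (digital numbers) or calibrated
#' reflectance.
#'
#' @param data numeric 3-D array, `rows x cols x channels`
#' @param grid a [build_wavelength_grid()] object; its length must equal the
#'   third dimension of `data`
#' @param kind `"raw_counts"` or `"reflectance"`
#' @param metadata free-form named list (exposure plan id, seed, provenance...)
#' @param mask optional logical array of the same dimensions as `data`;
#'   `TRUE` marks a valid pixel-channel entry. `NULL` means all valid.
#' @param flags optional integer array of per-entry condition codes (see
#'   [make_validity_mask()]); kept alongside the mask, never applied silently.
#' @return an object of class `hypercube`
#' @export
hypercube <- function(data, grid, kind = c("raw_counts", "reflectance"),
                      metadata = list(), mask = NULL, flags = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a rows x cols x channels array")
  if (!inherits(grid, "wavelength_grid"))
    stop("grid must be a wavelength_grid")
  if (dim(data)[3L] != length(grid$centers))
    stop(sprintf("channel mismatch: data has %d bands, grid %d centers",
                 dim(data)[3L], length(grid$centers)))
  if (!is.null(mask) && !identical(dim(mask), dim(data)))
    stop("mask dimensions must match data")
  if (kind == "raw_counts" && any(data < 0, na.rm = TRUE))
    stop("raw counts must be nonnegative")
  structure(list(data = data, grid = grid, kind = kind, metadata = metadata,
                 mask = mask, flags = flags),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d channels [%s], kind = %s\n",
              d[1], d[2], d[3], format(x$grid), x$kind))
  if (!is.null(x$mask))
    cat(sprintf("  validity mask: %.2f%% valid\n", 100 * mean(x$mask)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

# pixels as an (rows*cols) x channels matrix, row-major pixel order
# (pixel index k corresponds to row (k-1) %/% cols, col (k-1) %% cols)
cube_pixel_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  m
}

# inverse of cube_pixel_matrix
pixel_matrix_to_array <- function(m, rows, cols) {
  aperm(array(m, dim = c(cols, rows, ncol(m))), c(2L, 1L, 3L))
}

## ---------------------------------------------------------------------------
## ENVI-convention storage: text header (.hdr) + band-sequential raw binary.
## Doubles (data type 5) are used for cubes so that write->read is bit-exact;
## label rasters use byte (data type 1).

envi_header_text <- function(samples, lines, bands, data_type, interleave,
                             wavelengths = NULL, extra = list()) {
  out <- c("ENVI",
           sprintf("samples = %d", samples),
           sprintf("lines = %d", lines),
           sprintf("bands = %d", bands),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0")
  if (!is.null(wavelengths)) {
    out <- c(out, "wavelength units = Nanometers",
             paste0("wavelength = { ",
                    paste(format(wavelengths, trim = TRUE, digits = 12),
                          collapse = " , "), " }"))
  }
  for (k in names(extra))
    out <- c(out, sprintf("%s = %s", k, extra[[k]]))
  out
}

parse_envi_header <- function(hdr_path) {
  ln <- readLines(hdr_path, warn = FALSE)
  if (!length(ln) || trimws(ln[1]) != "ENVI")
    stop("not an ENVI header: ", hdr_path)
  fields <- list()
  # records are single lines except { ... } blocks, which may span lines
  pieces <- ln[-1]
  buf <- character(0); open <- FALSE
  recs <- character(0)
  for (p in pieces) {
    if (open) {
      buf <- c(buf, p)
      if (grepl("\\}", p)) { recs <- c(recs, paste(buf, collapse = " ")); open <- FALSE }
    } else if (grepl("\\{", p) && !grepl("\\}", p)) {
      buf <- p; open <- TRUE
    } else recs <- c(recs, p)
  }
  for (r in recs) {
    if (!grepl("=", r)) next
    key <- trimws(sub("=.*$", "", r))
    val <- trimws(sub("^[^=]*=", "", r))
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_brace_numbers <- function(val) {
  inner <- gsub("[{}]", "", val)
  as.numeric(strsplit(inner, ",")[[1]])
}

#' Write a hypercube to disk (ENVI header + band-sequential binary)
#'
#' @param cube a [hypercube()]
#' @param path path of the binary payload; the header is written to
#'   `paste0(path, ".hdr")`
#' @return `path`, invisibly
#' @export
write_hypercube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  extra <- list(`cube kind` = cube$kind)
  for (k in names(cube$metadata)) {
    v <- cube$metadata[[k]]
    if (is.atomic(v) && length(v) == 1L)
      extra[[paste0("meta ", k)]] <- as.character(v)
  }
  hdr <- envi_header_text(samples = d[2], lines = d[1], bands = d[3],
                          data_type = 5L, interleave = "bsq",
                          wavelengths = cube$grid$centers, extra = extra)
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: for each band, lines of samples (row-major within band)
  writeBin(as.vector(aperm(cube$data, c(2L, 1L, 3L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

#' Read a hypercube written by [write_hypercube()]
#'
#' Checks that the declared dimensions match the binary payload and that a
#' wavelength list is present; errors otherwise.
#'
#' @param path payload path (header expected at `paste0(path, ".hdr")`)
#' @return a [hypercube()]
#' @export
read_hypercube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need) if (is.null(h[[k]])) stop("header missing field: ", k)
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  if (is.null(h[["wavelength"]])) stop("header missing wavelength list")
  wl <- envi_brace_numbers(h[["wavelength"]])
  if (length(wl) != bands)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 bands, length(wl)))
  il <- tolower(h[["interleave"]])
  sz <- switch(as.character(dt), "1" = 1L, "4" = 4L, "5" = 8L,
               stop("unsupported ENVI data type: ", dt))
  n <- samples * lines * bands
  payload_bytes <- file.size(path)
  if (payload_bytes != n * sz)
    stop(sprintf("payload size %d bytes inconsistent with header (%d expected)",
                 payload_bytes, n * sz))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- if (dt == 1L) as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
          else readBin(con, "double", n = n, size = sz, endian = "little")
  # normalise interleave to BSQ order on read
  arr <- switch(il,
    bsq = aperm(array(vals, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bip = aperm(array(vals, dim = c(bands, samples, lines)), c(3L, 2L, 1L)),
    bil = aperm(array(vals, dim = c(samples, bands, lines)), c(3L, 1L, 2L)),
    stop("unsupported interleave: ", il))
  step <- if (length(wl) > 1L) wl[2] - wl[1] else 1
  grid <- build_wavelength_grid(wl[1], wl[length(wl)], step)
  if (!isTRUE(all.equal(grid$centers, wl)))
    grid$centers <- wl  # non-uniform grids kept verbatim
  kind <- if (!is.null(h[["cube kind"]])) h[["cube kind"]] else "raw_counts"
  meta <- list()
  for (k in names(h))
    if (startsWith(k, "meta "))
      meta[[sub("^meta ", "", k)]] <- utils::type.convert(h[[k]], as.is = TRUE)
  hypercube(arr, grid, kind = kind, metadata = meta)
}

## ---------------------------------------------------------------------------
## Label maps: single-band ENVI byte raster + sidecar text legend.

#' Construct a label map
#'
#' Integer raster of per-pixel class codes with a legend. Code `0` is reserved
#' for invalid/unlabeled pixels and need not appear in the legend.
#'
#' @param labels integer matrix (`rows x cols`) of class codes
#' @param legend named integer vector mapping class names to codes, or a named
#'   character vector `code -> name`; internally stored as `code -> name`
#' @return an object of class `label_map`
#' @export
label_map <- function(labels, legend) {
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (is.numeric(legend) && !is.null(names(legend)))
    legend <- stats::setNames(names(legend), as.character(as.integer(legend)))
  codes <- sort(unique(as.vector(labels)))
  codes <- codes[codes != 0L]
  missing <- setdiff(as.character(codes), names(legend))
  if (length(missing))
    stop("raster codes absent from legend: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes (+%d invalid px)\n",
              nrow(x$labels), ncol(x$labels), length(x$legend),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Per-class names of a label map
#' @param lm a [label_map()]
#' @return character vector of class names ordered by code
#' @export
label_classes <- function(lm) {
  unname(lm$legend[order(as.integer(names(lm$legend)))])
}

#' Write / read a label raster (ENVI byte image + text legend)
#' @param lm a [label_map()]
#' @param path payload path; header at `path.hdr`, legend at `path.legend`
#' @return `path` invisibly
#' @export
write_label_map <- function(lm, path) {
  d <- dim(lm$labels)
  if (any(lm$labels < 0L | lm$labels > 255L))
    stop("byte raster supports codes 0..255")
  hdr <- envi_header_text(samples = d[2], lines = d[1], bands = 1L,
                          data_type = 1L, interleave = "bsq")
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.integer(t(lm$labels)), con, size = 1L)
  leg <- sprintf("%s\t%s", names(lm$legend), unname(lm$legend))
  writeLines(leg, paste0(path, ".legend"))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = samples * lines, size = 1L, signed = FALSE)
  labels <- matrix(v, nrow = lines, ncol = samples, byrow = TRUE)
  leg_lines <- readLines(paste0(path, ".legend"), warn = FALSE)
  parts <- strsplit(leg_lines, "\t")
  legend <- stats::setNames(vapply(parts, `[`, "", 2L),
                            vapply(parts, `[`, "", 1L))
  label_map(labels, legend)
}
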