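#' Build a wavelength grid for a channel-scanned hypercube
#'
#' A staring hyperspectral imager scans the tunable filter's center wavelength
#' (CWL) over a closed range in fixed steps; each step becomes one channel of
#' the hypercube. The default acquisition scans 420--730 nm in 5 nm steps,
#' which yields 63 channels.
#'
#' The number of channels is `floor((stop_nm - start_nm) / step_nm) + 1`;
#' the last center never exceeds `stop_nm`.
#'
#' @param start_nm first center wavelength (nm)
#' @param stop_nm last admissible center wavelength (nm); must be >= `start_nm`
#' @param step_nm scan step (nm); must be > 0
#' @return an object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `centers` (strictly increasing channel centers).
#' @examples
#' g <- build_wavelength_grid(420, 730, 5)
#' length(g$centers)  # 63
#' @export
build_wavelength_grid <- function(start_nm, stop_nm, step_nm) {
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0)
    stop("step_nm must be a single positive number")
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || stop_nm < start_nm)
    stop("stop_nm must be >= start_nm")
  n <- floor((stop_nm - start_nm) / step_nm) + 1L
  centers <- start_nm + (seq_len(n) - 1L) * step_nm
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         centers = centers),
    class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$centers)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d channels\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$centers)))
  invisible(x)
}

#' @export
format.wavelength_grid <- function(x, ...) {
  sprintf("%g-%g nm / %g nm (%d ch)", x$start_nm, x$stop_nm, x$step_nm,
          length(x$centers))
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$centers, b$centers, tolerance = 1e-9))
}
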