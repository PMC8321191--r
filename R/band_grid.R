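#' Uniform spectral band grid
#'
#' A band grid discretizes a spectral axis (energy in keV for X-ray data,
#' wavelength in nm for reflectance data) into `n_bins` uniform bins; all
#' spectra in the package are sampled at bin centers.
#'
#' @param n_bins Number of spectral bins (>= 2).
#' @param axis_min,axis_max Physical range of the axis; `axis_max > axis_min`.
#' @param unit `"keV"` or `"nm"`.
#' @return An object of class `band_grid` with fields `n_bins`, `axis_min`,
#'   `axis_max`, `unit` and `centers` (strictly increasing bin centers).
#' @examples
#' g <- make_band_grid(200, 450, 2400, "nm")
#' diff(g$centers)[1]  # bin width 9.75 nm
#' @export
make_band_grid <- function(n_bins, axis_min, axis_max, unit = c("keV", "nm")) {
  unit <- match.arg(unit)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("n_bins must be a single integer >= 2")
  n_bins <- as.integer(n_bins)
  if (!(axis_max > axis_min))
    stop("axis_max must exceed axis_min")
  width <- (axis_max - axis_min) / n_bins
  centers <- axis_min + (seq_len(n_bins) - 0.5) * width
  structure(
    list(n_bins = n_bins, axis_min = axis_min, axis_max = axis_max,
         unit = unit, centers = centers, width = width),
    class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("band_grid: %d bins, %.4g-%.4g %s (width %.4g %s)\n",
              x$n_bins, x$axis_min, x$axis_max, x$unit, x$width, x$unit))
  invisible(x)
}

#' Index of the bin containing an axis value
#'
#' @param grid A `band_grid`.
#' @param value Axis value (same unit as the grid).
#' @return 1-based bin index, clamped to the grid.
#' @export
band_index <- function(grid, value) {
  stopifnot(inherits(grid, "band_grid"))
  idx <- floor((value - grid$axis_min) / grid$width) + 1
  pmin(pmax(as.integer(idx), 1L), grid$n_bins)
}

grids_equal <- function(a, b) {
  a$n_bins == b$n_bins && a$unit == b$unit &&
    isTRUE(all.equal(a$centers, b$centers, tolerance = 1e-12))
}
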