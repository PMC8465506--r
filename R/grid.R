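#' Construct a wavelength (or wavenumber) grid
#'
#' Builds the shared spectral axis on which all spectra in a collection are
#' sampled. Two endpoint conventions are in instrument-software use and both
#' are supported explicitly: `count_floor_steps` places
#' `floor((stop - start) / step)` points at `start + k * step`
#' (`k = 1, 2, ...`, the start point itself excluded), while
#' `inclusive_points` places `1 + floor((stop - start) / step)` points
#' starting at `start`. A visible-NIR transmittance axis of 550--985 nm at a
#' 0.21 nm increment yields 2071 variables under the first dialect; an FT-NIR
#' axis of 4000--10000 cm-1 at 3.856 cm-1 yields 1557 variables under the
#' second.
#'
#' @param start,stop axis endpoints (same unit as `unit`); `stop > start`.
#' @param step increment between successive points; positive.
#' @param unit `"nm"` (wavelength) or `"cm-1"` (wavenumber).
#' @param dialect endpoint convention, `"count_floor_steps"` or
#'   `"inclusive_points"`.
#' @return An object of class `wavelength_grid`: a list with `values`
#'   (strictly increasing numeric vector), `unit`, `start`, `stop`, `step`
#'   and `dialect`.
#' @examples
#' length(make_grid(550, 985, 0.21)$values)       # 2071
#' length(make_grid(4000, 10000, 3.856, unit = "cm-1",
#'                  dialect = "inclusive_points")$values)  # 1557
#' @export
make_grid <- function(start, stop, step, unit = c("nm", "cm-1"),
                      dialect = c("count_floor_steps", "inclusive_points")) {
  unit <- match.arg(unit)
  dialect <- match.arg(dialect)
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step))
    stop("grid endpoints and step must be finite")
  if (step <= 0) stop("step must be positive")
  if (stop <= start) stop("stop must exceed start")
  n_steps <- floor((stop - start) / step + 1e-9)
  values <- switch(dialect,
    count_floor_steps = start + step * seq_len(n_steps),
    inclusive_points  = start + step * (0:n_steps))
  structure(
    list(values = values, unit = unit, start = start, stop = stop,
         step = step, dialect = dialect),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d points, %.4g to %.4g %s (step %.4g, %s)\n",
              length(x$values), min(x$values), max(x$values), x$unit,
              x$step, x$dialect))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  v <- grid$values
  if (any(!is.finite(v)) || any(v <= 0))
    stop("grid values must be finite and positive")
  d <- diff(v)
  if (any(d <= 0)) stop("grid values must be strictly increasing")
  if (max(abs(d - grid$step)) > 1e-9 * grid$step)
    stop("grid declared uniform but successive differences deviate from step")
  invisible(grid)
}

# grid for arbitrary (possibly non-uniform) values, used when reading files
grid_from_values <- function(values, unit = "nm") {
  d <- diff(values)
  if (length(values) < 2 || any(d <= 0))
    stop("wavelength values must be strictly increasing")
  uniform <- max(abs(d - d[1])) <= 1e-9 * d[1]
  structure(
    list(values = values, unit = unit,
         start = values[1], stop = values[length(values)],
         step = if (uniform) d[1] else NA_real_,
         dialect = "inclusive_points"),
    class = "wavelength_grid")
}
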