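#' Wavelength grid of a hyperspectral acquisition
#'
#' Constructs the ordered vector of band centers used throughout the
#' package. The default grid matches a visible/NIR snapscan acquisition:
#' 470--900 nm sampled every 3 nm, giving 144 bands (the last band center,
#' 899 nm, is the largest value `start + k * step` not exceeding `stop`).
#'
#' @param start First band center in nm.
#' @param stop Upper limit in nm (inclusive if hit exactly by the step).
#' @param step Band spacing in nm; must be > 0.
#' @return An object of class `wavelength_grid`: a list with fields
#'   `start`, `stop`, `step` and `values` (strictly increasing numeric
#'   vector of band centers in nm).
#' @examples
#' g <- wavelength_grid()
#' length(g$values) # 144
#' @export
wavelength_grid <- function(start = 470, stop = 900, step = 3) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1)
  if (step <= 0) stop("wavelength_grid: `step` must be > 0", call. = FALSE)
  if (stop < start) stop("wavelength_grid: `stop` must be >= `start`", call. = FALSE)
  values <- seq(start, stop, by = step)
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d bands\n",
              x$start, max(x$values), x$step, length(x$values)))
  invisible(x)
}

# Coerce a grid or bare numeric vector to the band-center vector.
grid_values <- function(grid) {
  if (inherits(grid, "wavelength_grid")) return(grid$values)
  if (is.numeric(grid) && length(grid) > 0) {
    if (any(diff(grid) <= 0)) {
      stop("wavelengths must be strictly increasing", call. = FALSE)
    }
    return(as.numeric(grid))
  }
  stop("expected a `wavelength_grid` or a numeric wavelength vector",
       call. = FALSE)
}
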