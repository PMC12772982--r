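# Wavelength grid and hypercube containers.

#' Build a regular wavelength grid
#'
#' A hyperspectral cube binds its third (spectral) axis to a regular grid of
#' band-center wavelengths. The push-broom systems this package targets sample
#' 500--995 nm in 5 nm steps, i.e. 100 bands.
#'
#' @param start_nm first band center in nanometers.
#' @param step_nm band spacing in nanometers; must be positive.
#' @param end_nm last band center in nanometers; `end_nm - start_nm` must be an
#'   integer multiple of `step_nm`.
#' @return A `wavelength_grid` object with fields `start_nm`, `step_nm`,
#'   `n_bands` and the derived vector `centers_nm`.
#' @examples
#' g <- build_grid(500, 5, 995)
#' g$n_bands  # 100
#' @export
build_grid <- function(start_nm, step_nm, end_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(step_nm), is.numeric(end_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (end_nm < start_nm) stop("end_nm must be >= start_nm")
  k <- (end_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-9) {
    stop("(end_nm - start_nm) must be divisible by step_nm")
  }
  n <- as.integer(round(k)) + 1L
  structure(
    list(start_nm = start_nm, step_nm = step_nm, n_bands = n,
         centers_nm = start_nm + step_nm * (seq_len(n) - 1)),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d bands\n",
              x$start_nm, x$centers_nm[x$n_bands], x$step_nm, x$n_bands))
  invisible(x)
}

#' Indices of grid bands inside a wavelength window
#'
#' @param grid a [build_grid()] object.
#' @param lo_nm,hi_nm inclusive window bounds in nanometers.
#' @return Integer band indices; errors if the window contains no band.
#' @export
band_window <- function(grid, lo_nm, hi_nm) {
  stopifnot(inherits(grid, "wavelength_grid"), lo_nm <= hi_nm)
  idx <- which(grid$centers_nm >= lo_nm & grid$centers_nm <= hi_nm)
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] nm contains no grid band", lo_nm, hi_nm))
  }
  idx
}

#' Construct a hypercube
#'
#' Wraps an `H x W x B` reflectance array (values in \[0, 1\]) together with
#' its wavelength grid and the physical pixel pitch. Axis convention: first
#' array dimension is image row (y), second is column (x), third is band.
#'
#' @param reflectance numeric array of dimension `H x W x B`.
#' @param grid a [build_grid()] object with `n_bands == B`.
#' @param pixel_pitch_mm spatial sampling in millimeters per pixel (metadata;
#'   default 0.45 as for a 640x480 tissue imager at 50 cm).
#' @return A `hypercube` object.
#' @export
hypercube <- function(reflectance, grid, pixel_pitch_mm = 0.45) {
  stopifnot(is.array(reflectance), length(dim(reflectance)) == 3L,
            inherits(grid, "wavelength_grid"))
  if (dim(reflectance)[3] != grid$n_bands) {
    stop("third array dimension must equal grid$n_bands")
  }
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  structure(list(reflectance = reflectance, grid = grid,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%g-%g nm), %.2f mm/px\n",
              d[1], d[2], d[3], x$grid$start_nm,
              x$grid$centers_nm[x$grid$n_bands], x$pixel_pitch_mm))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$reflectance)
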