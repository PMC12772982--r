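# Spectral feature extraction: region mean spectra, z-scoring, and band-ratio
# chromophore indices.
#
# The four tissue indices follow the structure of commercial HSI perfusion
# systems: each compares mean absorbance (-log10 reflectance) inside two
# wavelength windows and rescales the raw contrast to [0, 1]. The vendor's
# exact constants are proprietary; the window defaults below follow the
# published system description and live entirely in configuration, so only
# signs and orderings of index differences are meaningful, not absolute
# values.

#' Absorbance transform of a hypercube
#'
#' `A = -log10(max(R, floor))`, monotone decreasing in reflectance. The floor
#' guards against `log(0)`; at realistic tissue reflectance it is inactive.
#'
#' @param cube a [hypercube()].
#' @param floor small positive reflectance clamp (default 1e-4, i.e. maximum
#'   absorbance 4).
#' @return Numeric array `H x W x B` of absorbance values.
#' @export
absorbance <- function(cube, floor = 1e-4) {
  stopifnot(inherits(cube, "hypercube"), floor > 0)
  -log10(pmax(cube$reflectance, floor))
}

#' Mean reflectance spectrum over a masked region
#'
#' @param cube a [hypercube()].
#' @param mask binary `H x W` matrix with at least one set pixel.
#' @return Numeric vector of length B: per-band arithmetic mean over masked
#'   pixels, named by band center wavelength.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  mask <- as_binary_mask(mask)
  d <- dim(cube$reflectance)
  if (!identical(dim(mask), d[1:2])) stop("mask shape must match cube spatial shape")
  idx <- which(mask == 1L)
  if (length(idx) == 0L) stop("mask is empty")
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  s <- colMeans(flat[idx, , drop = FALSE])
  names(s) <- cube$grid$centers_nm
  s
}

#' Z-score a spectrum against its own mean
#'
#' @param s numeric spectrum.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return `(s - mean(s)) / sd(s)`; mean 0 and the chosen-convention sd 1.
#'   Errors on a constant spectrum.
#' @export
zscore_spectrum <- function(s, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(s), length(s) >= 2L)
  ctr <- s - mean(s)
  ss <- sqrt(sum(ctr^2) / if (sd_type == "population") length(s) else length(s) - 1L)
  if (ss == 0) stop("constant spectrum cannot be z-scored")
  ctr / ss
}

#' Define a band-ratio tissue index
#'
#' @param name index label, conventionally one of `"TWI"`, `"THI"`, `"StO2"`,
#'   `"NIR"`.
#' @param numerator_nm,denominator_nm length-2 `c(lo, hi)` wavelength windows
#'   in nanometers.
#' @param scale length-2 `c(raw_min, raw_max)` mapping the raw band contrast
#'   linearly onto \[0, 1\] (values outside are clipped).
#' @param mode `"difference"` (mean absorbance numerator minus denominator;
#'   default) or `"quotient"`.
#' @return A `band_ratio_def` object.
#' @export
band_ratio_def <- function(name, numerator_nm, denominator_nm,
                           scale = c(-1, 1), mode = c("difference", "quotient")) {
  mode <- match.arg(mode)
  stopifnot(length(numerator_nm) == 2L, length(denominator_nm) == 2L,
            numerator_nm[1] <= numerator_nm[2],
            denominator_nm[1] <= denominator_nm[2],
            length(scale) == 2L, scale[1] < scale[2])
  structure(list(name = name, numerator_nm = numerator_nm,
                 denominator_nm = denominator_nm, scale = scale, mode = mode),
            class = "band_ratio_def")
}

#' Default tissue index definitions
#'
#' Window placements follow the published description of the imaging system's
#' index bands: StO2 contrasts an oxygenation-sensitive visible window against
#' the deoxyhemoglobin NIR band, NIR perfusion contrasts 655--735 nm against
#' 825--925 nm, THI (hemoglobin) contrasts the 530--590 nm hemoglobin soret
#' region against a hemoglobin-quiet NIR window, and TWI (water) contrasts a
#' pre-water-peak window against the 955--980 nm water absorption band.
#' `scale` constants are package choices that keep phantom values inside
#' (0, 1) without clipping.
#'
#' @return Named list of four [band_ratio_def()]s: `TWI`, `THI`, `StO2`,
#'   `NIR`.
#' @export
default_index_defs <- function() {
  list(
    TWI  = band_ratio_def("TWI",  c(955, 980), c(880, 900), scale = c(-0.5, 0.5)),
    THI  = band_ratio_def("THI",  c(530, 590), c(785, 825), scale = c(-0.5, 1.5)),
    StO2 = band_ratio_def("StO2", c(570, 590), c(740, 780), scale = c(-0.5, 1.5)),
    NIR  = band_ratio_def("NIR",  c(655, 735), c(825, 925), scale = c(-0.5, 0.5))
  )
}

#' Compute one per-pixel tissue index map
#'
#' Per pixel, `raw` is the mean absorbance inside the numerator window minus
#' (difference mode) or divided by (quotient mode) the mean absorbance inside
#' the denominator window; the map value is
#' `clip((raw - raw_min) / (raw_max - raw_min), 0, 1)`.
#'
#' @param cube a [hypercube()].
#' @param def a [band_ratio_def()]; both windows must contain at least one
#'   grid band.
#' @param floor absorbance reflectance floor, see [absorbance()].
#' @return An `index_map` object: `values` (`H x W` in \[0,1\]),
#'   `index_name`, `def`.
#' @export
compute_index <- function(cube, def, floor = 1e-4) {
  stopifnot(inherits(cube, "hypercube"), inherits(def, "band_ratio_def"))
  A <- absorbance(cube, floor)
  ni <- band_window(cube$grid, def$numerator_nm[1], def$numerator_nm[2])
  di <- band_window(cube$grid, def$denominator_nm[1], def$denominator_nm[2])
  d <- dim(A)
  flat <- matrix(A, d[1] * d[2], d[3])
  num <- rowMeans(flat[, ni, drop = FALSE])
  den <- rowMeans(flat[, di, drop = FALSE])
  raw <- if (def$mode == "difference") num - den else num / pmax(den, 1e-12)
  v <- pmin(pmax((raw - def$scale[1]) / (def$scale[2] - def$scale[1]), 0), 1)
  structure(list(values = matrix(v, d[1], d[2]), index_name = def$name,
                 def = def),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<index_map> %s, %d x %d px, range [%.3f, %.3f]\n",
              x$index_name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Compute all configured tissue index maps
#'
#' @param cube a [hypercube()].
#' @param defs named list of [band_ratio_def()]s (default
#'   [default_index_defs()]).
#' @param floor absorbance floor.
#' @return Named list of `index_map`s, one per definition.
#' @export
compute_all_indices <- function(cube, defs = default_index_defs(), floor = 1e-4) {
  stopifnot(is.list(defs), length(defs) >= 1L)
  out <- lapply(defs, function(d) compute_index(cube, d, floor))
  names(out) <- vapply(defs, function(d) d$name, character(1))
  out
}

#' Mean index value over a masked region
#'
#' @param map an `index_map` from [compute_index()].
#' @param mask binary matrix, same shape, nonempty.
#' @return Scalar in \[0, 1\].
#' @export
region_mean_index <- function(map, mask) {
  stopifnot(inherits(map, "index_map"))
  mask <- as_binary_mask(mask)
  if (!identical(dim(mask), dim(map$values))) stop("mask shape mismatch")
  idx <- which(mask == 1L)
  if (length(idx) == 0L) stop("mask is empty")
  mean(map$values[idx])
}
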