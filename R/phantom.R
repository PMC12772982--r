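# Seeded hyperspectral phantom scenes with known ground truth.
#
# The phantom is the package's stand-in for unavailable clinical data: a
# "cervix" disc whose lesion subregions carry elevated hemoglobin and water
# concentrations, imaged under a single-layer Beer-Lambert reflectance model
#   R(x, y, lambda) = R_base(lambda) * exp(-sum_i c_i(x, y) * eps_i(lambda))
# plus Gaussian sensor noise, clipped to [0, 1]. No scattering model: the
# simplest forward model that makes band-ratio indices respond with the
# correct sign to injected chromophore changes.

#' Chromophore absorption model
#'
#' Absorption curve built as a sum of Gaussian peaks; nonnegative everywhere
#' by construction. Peak placements mimic where the real chromophores absorb
#' (hemoglobin visible doublet, deoxyhemoglobin near-infrared band, water
#' beyond 950 nm) without claiming physical accuracy -- they exist to put
#' signal in the windows the tissue indices read.
#'
#' @param name label.
#' @param peaks data.frame with columns `center_nm`, `width_nm`,
#'   `amplitude` (all positive).
#' @return A `chromophore` object.
#' @export
chromophore <- function(name, peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("center_nm", "width_nm", "amplitude") %in% names(peaks)),
            all(peaks$width_nm > 0), all(peaks$amplitude >= 0))
  structure(list(name = name, peaks = peaks), class = "chromophore")
}

#' Evaluate a chromophore's absorption at given wavelengths
#'
#' @param chrom a [chromophore()].
#' @param wavelengths_nm numeric vector.
#' @return Nonnegative numeric vector (arbitrary absorption units).
#' @export
absorption_curve <- function(chrom, wavelengths_nm) {
  stopifnot(inherits(chrom, "chromophore"))
  out <- numeric(length(wavelengths_nm))
  for (i in seq_len(nrow(chrom$peaks))) {
    p <- chrom$peaks[i, ]
    out <- out + p$amplitude *
      exp(-((wavelengths_nm - p$center_nm) / p$width_nm)^2 / 2)
  }
  out
}

#' Default phantom chromophores
#'
#' Oxyhemoglobin as a Gaussian doublet near 542/577 nm, deoxyhemoglobin near
#' 555 and 760 nm, water near 970 nm.
#'
#' @return Named list of three [chromophore()]s: `oxyhemoglobin`,
#'   `deoxyhemoglobin`, `water`.
#' @export
default_chromophores <- function() {
  list(
    oxyhemoglobin = chromophore("oxyhemoglobin", data.frame(
      center_nm = c(542, 577), width_nm = c(12, 12), amplitude = c(1.0, 0.9))),
    deoxyhemoglobin = chromophore("deoxyhemoglobin", data.frame(
      center_nm = c(555, 760), width_nm = c(15, 30), amplitude = c(0.8, 0.35))),
    water = chromophore("water", data.frame(
      center_nm = 970, width_nm = 35, amplitude = 1.0))
  )
}

# smooth, mildly sloped baseline reflectance of bloodless tissue
default_baseline_reflectance <- function(wavelengths_nm) {
  0.5 + 0.1 * (wavelengths_nm - 500) / 495
}

#' Specify a phantom scene
#'
#' @param image_height,image_width scene size in pixels.
#' @param grid a [build_grid()] wavelength grid.
#' @param disc_center,disc_radius "cervix" disc geometry in pixels
#'   (0-based (x, y) center).
#' @param lesion_regions list of lesion entries, each
#'   `list(class = "major"|"minor", polygon = n x 2 vertex matrix,
#'   multipliers = named concentration multipliers)`; every polygon must lie
#'   inside the disc.
#' @param baseline_concentrations named nonnegative vector, one entry per
#'   chromophore, applied everywhere inside the disc.
#' @param chromophores named list of [chromophore()]s.
#' @param noise_sd Gaussian sensor noise sd in reflectance units.
#' @param background_reflectance flat reflectance outside the disc.
#' @param seed integer seed; the cube generator is bit-reproducible in it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_height = 96L, image_width = 96L,
                         grid = build_grid(500, 5, 995),
                         disc_center = c(48, 48), disc_radius = 36,
                         lesion_regions = NULL,
                         baseline_concentrations =
                           c(oxyhemoglobin = 0.30, deoxyhemoglobin = 0.20,
                             water = 0.40),
                         chromophores = default_chromophores(),
                         noise_sd = 0.01,
                         background_reflectance = 0.15,
                         seed = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"), grid$n_bands >= 1L,
            image_height >= 8L, image_width >= 8L,
            disc_radius > 0, noise_sd >= 0,
            all(baseline_concentrations >= 0),
            all(names(baseline_concentrations) %in% names(chromophores)))
  if (is.null(lesion_regions)) {
    lesion_regions <- default_lesion_regions(disc_center, disc_radius)
  }
  for (lr in lesion_regions) {
    stopifnot(lr$class %in% c("major", "minor"), is.matrix(lr$polygon),
              all(lr$multipliers >= 0))
    d <- sqrt((lr$polygon[, 1] - disc_center[1])^2 +
              (lr$polygon[, 2] - disc_center[2])^2)
    if (any(d > disc_radius)) stop("lesion polygon extends outside the cervix disc")
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 grid = grid, disc_center = disc_center,
                 disc_radius = disc_radius, lesion_regions = lesion_regions,
                 baseline_concentrations = baseline_concentrations,
                 chromophores = chromophores, noise_sd = noise_sd,
                 background_reflectance = background_reflectance,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# two lesions (one major, one minor) placed off-center inside the disc;
# multipliers encode elevated hemoglobin and water in dysplastic tissue
default_lesion_regions <- function(disc_center, disc_radius) {
  list(
    list(class = "major",
         polygon = circle_polygon(disc_center[1] - 0.35 * disc_radius,
                                  disc_center[2] - 0.20 * disc_radius,
                                  0.33 * disc_radius),
         multipliers = c(oxyhemoglobin = 2.0, deoxyhemoglobin = 2.0,
                         water = 1.8)),
    list(class = "minor",
         polygon = circle_polygon(disc_center[1] + 0.38 * disc_radius,
                                  disc_center[2] + 0.28 * disc_radius,
                                  0.26 * disc_radius),
         multipliers = c(oxyhemoglobin = 1.5, deoxyhemoglobin = 1.5,
                         water = 1.4))
  )
}

#' Generate a phantom hypercube with ground-truth annotations
#'
#' Renders the Beer-Lambert reflectance model of `spec` onto the wavelength
#' grid, adds seeded Gaussian noise, clips to \[0, 1\], and returns the cube
#' together with the exact lesion masks and the healthy reference mask
#' (disc minus lesions). Identical specs (including seed) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `cube` (a [hypercube()]) and `truth` (an
#'   [annotation_set()] in the `"hsi"` frame carrying the region polygons as
#'   attributes for downstream perturbation).
#' @export
generate_phantom_cube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$grid$n_bands < 1L) stop("wavelength grid is empty")
  h <- spec$image_height; w <- spec$image_width
  shape <- c(h, w)
  wl <- spec$grid$centers_nm
  B <- spec$grid$n_bands

  disc_poly <- circle_polygon(spec$disc_center[1], spec$disc_center[2],
                              spec$disc_radius, n_vertices = 96L)
  disc <- rasterize_polygon(disc_poly, shape)

  # per-class ground-truth lesion masks
  class_masks <- list()
  for (cl in c("major", "minor")) {
    polys <- Filter(function(lr) lr$class == cl, spec$lesion_regions)
    if (length(polys)) {
      m <- Reduce(function(a, b) pmax(a, b),
                  lapply(polys, function(lr) rasterize_polygon(lr$polygon, shape)))
      class_masks[[cl]] <- m
    }
  }
  lesion_any <- if (length(class_masks)) {
    Reduce(function(a, b) pmax(a, b), class_masks)
  } else matrix(0L, h, w)
  healthy <- disc * (1L - lesion_any)

  # concentration field per chromophore: baseline inside disc, multiplied
  # inside each lesion (max multiplier wins on overlap)
  chrom_names <- names(spec$chromophores)
  conc <- matrix(0, h * w, length(chrom_names),
                 dimnames = list(NULL, chrom_names))
  inside <- which(disc == 1L)
  for (cn in chrom_names) {
    base_c <- if (cn %in% names(spec$baseline_concentrations))
      spec$baseline_concentrations[[cn]] else 0
    mult <- matrix(1, h, w)
    for (lr in spec$lesion_regions) {
      if (cn %in% names(lr$multipliers)) {
        lm <- rasterize_polygon(lr$polygon, shape)
        mult <- pmax(mult, 1 + (lr$multipliers[[cn]] - 1) * lm)
      }
    }
    cc <- matrix(0, h, w)
    cc[inside] <- base_c * mult[inside]
    conc[, cn] <- as.vector(cc)
  }

  eps <- vapply(spec$chromophores, absorption_curve,
                numeric(B), wavelengths_nm = wl)   # B x n_chrom
  absorb <- conc %*% t(eps)                        # (h*w) x B
  rbase <- default_baseline_reflectance(wl)
  refl <- exp(-absorb) * rep(rbase, each = h * w)
  # dark background outside the disc
  outside <- which(disc == 0L)
  refl[outside, ] <- spec$background_reflectance

  if (spec$noise_sd > 0) {
    set.seed(derive_subseed(spec$seed, 101L))
    refl <- refl + stats::rnorm(length(refl), sd = spec$noise_sd)
  }
  refl <- clip01(refl)
  cube <- hypercube(array(refl, dim = c(h, w, B)), spec$grid)

  masks <- class_masks
  masks$healthy <- healthy
  truth <- annotation_set(masks, subject_id = "phantom",
                          examiner_id = "truth", frame = "hsi")
  attr(truth, "regions") <- lapply(spec$lesion_regions, function(lr)
    list(class = lr$class, polygon = lr$polygon))
  attr(truth, "disc_polygon") <- disc_poly
  attr(truth, "shape") <- shape
  list(cube = cube, truth = truth)
}

#' Examiner noise model
#'
#' @param n_examiners number of simulated examiners (>= 1).
#' @param boundary_jitter_sd sd (pixels) of the smooth radial boundary
#'   displacement.
#' @param dilation_bias_range half-width (pixels) of each examiner's uniform
#'   over/under-segmentation bias.
#' @param omission_probability per-region probability that an examiner misses
#'   a lesion entirely, in \[0, 1\].
#' @param seed integer seed.
#' @return An `examiner_noise_spec` object.
#' @export
examiner_noise_spec <- function(n_examiners = 5L, boundary_jitter_sd = 3,
                                dilation_bias_range = 4,
                                omission_probability = 0.05, seed = 1L) {
  stopifnot(n_examiners >= 1L, boundary_jitter_sd >= 0,
            dilation_bias_range >= 0,
            omission_probability >= 0, omission_probability <= 1)
  structure(list(n_examiners = as.integer(n_examiners),
                 boundary_jitter_sd = boundary_jitter_sd,
                 dilation_bias_range = dilation_bias_range,
                 omission_probability = omission_probability,
                 seed = as.integer(seed)),
            class = "examiner_noise_spec")
}

# smooth periodic radial displacement with marginal sd `sd`: a low-order
# random Fourier series, so examiners over/under-segment in contiguous arcs
# rather than with per-vertex salt-and-pepper noise
smooth_radial_noise <- function(theta, sd, n_harmonics = 4L) {
  if (sd == 0) return(numeric(length(theta)))
  z <- numeric(length(theta))
  for (m in seq_len(n_harmonics)) {
    a <- stats::rnorm(1, sd = sd / sqrt(n_harmonics))
    b <- stats::rnorm(1, sd = sd / sqrt(n_harmonics))
    z <- z + a * cos(m * theta) + b * sin(m * theta)
  }
  z
}

# displace a star-shaped polygon radially about its centroid
perturb_polygon <- function(poly, jitter_sd, bias) {
  ctr <- polygon_centroid(poly)
  dx <- poly[, 1] - ctr[1]; dy <- poly[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  r2 <- pmax(0.5, r + smooth_radial_noise(th, jitter_sd) + bias)
  cbind(x = ctr[1] + r2 * cos(th), y = ctr[2] + r2 * sin(th))
}

#' Simulate imperfect examiner annotations of a phantom truth
#'
#' Each simulated examiner re-draws every lesion boundary with smoothed
#' radial jitter plus a personal uniform dilation/erosion bias, and misses a
#' region entirely with `omission_probability`. The healthy reference is the
#' examiner's own (jittered) view of the disc minus their lesion marks, so at
#' zero noise every examiner reproduces the truth exactly.
#'
#' @param truth the `truth` [annotation_set()] from [generate_phantom_cube()]
#'   (or one transformed by [transform_annotation_frame()]); must carry the
#'   region polygons.
#' @param noise an [examiner_noise_spec()].
#' @return List of `noise$n_examiners` [annotation_set()]s in the same frame.
#' @export
simulate_examiner_annotations <- function(truth, noise) {
  stopifnot(inherits(truth, "annotation_set"),
            inherits(noise, "examiner_noise_spec"))
  regions <- attr(truth, "regions")
  disc_poly <- attr(truth, "disc_polygon")
  shape <- attr(truth, "shape")
  if (is.null(regions) || is.null(disc_poly) || is.null(shape)) {
    stop("truth annotation set must carry region polygons ",
         "(generate it with generate_phantom_cube)")
  }
  if (length(regions) == 0L) stop("truth has no lesion regions")

  out <- vector("list", noise$n_examiners)
  for (e in seq_len(noise$n_examiners)) {
    set.seed(derive_subseed(noise$seed, 200L + e))
    bias <- if (noise$dilation_bias_range > 0)
      stats::runif(1, -noise$dilation_bias_range, noise$dilation_bias_range)
      else 0
    class_masks <- list()
    lesion_any <- matrix(0L, shape[1], shape[2])
    for (reg in regions) {
      omitted <- noise$omission_probability > 0 &&
        stats::runif(1) < noise$omission_probability
      if (omitted) next
      poly <- perturb_polygon(reg$polygon, noise$boundary_jitter_sd, bias)
      m <- rasterize_polygon(poly, shape)
      class_masks[[reg$class]] <- if (is.null(class_masks[[reg$class]]))
        m else pmax(class_masks[[reg$class]], m)
      lesion_any <- pmax(lesion_any, m)
    }
    # examiner's own view of the cervix boundary, jittered the same way
    disc_j <- perturb_polygon(disc_poly, noise$boundary_jitter_sd, bias)
    healthy <- rasterize_polygon(disc_j, shape) * (1L - lesion_any)
    class_masks$healthy <- healthy
    out[[e]] <- annotation_set(class_masks, subject_id = truth$subject_id,
                               examiner_id = sprintf("examiner_%d", e),
                               frame = truth$frame)
  }
  out
}

#' Transform a phantom truth annotation set into another image frame
#'
#' Maps the region and disc polygons through `H` and re-rasterizes at the
#' destination shape. Used to move ground truth from the HSI frame into the
#' simulated colposcope frame before examiner simulation.
#'
#' @param truth a polygon-carrying [annotation_set()].
#' @param H a [homography()] mapping the truth frame to the destination
#'   frame.
#' @param destination_shape integer `c(H, W)`.
#' @param frame label of the destination frame.
#' @return An [annotation_set()] in the destination frame, polygons attached.
#' @export
transform_annotation_frame <- function(truth, H, destination_shape,
                                       frame = "colposcope") {
  stopifnot(inherits(truth, "annotation_set"))
  regions <- attr(truth, "regions")
  disc_poly <- attr(truth, "disc_polygon")
  if (is.null(regions) || is.null(disc_poly)) {
    stop("annotation set does not carry region polygons")
  }
  shape <- as.integer(destination_shape)
  new_regions <- lapply(regions, function(reg)
    list(class = reg$class, polygon = project_points(H, reg$polygon)))
  new_disc <- project_points(H, disc_poly)

  class_masks <- list()
  lesion_any <- matrix(0L, shape[1], shape[2])
  for (reg in new_regions) {
    m <- rasterize_polygon(reg$polygon, shape)
    class_masks[[reg$class]] <- if (is.null(class_masks[[reg$class]]))
      m else pmax(class_masks[[reg$class]], m)
    lesion_any <- pmax(lesion_any, m)
  }
  class_masks$healthy <- rasterize_polygon(new_disc, shape) * (1L - lesion_any)
  out <- annotation_set(class_masks, subject_id = truth$subject_id,
                        examiner_id = truth$examiner_id, frame = frame)
  attr(out, "regions") <- new_regions
  attr(out, "disc_polygon") <- new_disc
  attr(out, "shape") <- shape
  out
}

#' Render a higher-resolution second view and landmark pairs
#'
#' Produces the simulated "colposcope" counterpart of a phantom cube: a
#' pseudo-RGB projection of the cube (three fixed bands near 620/540/500 nm)
#' resampled through the inverse of the true homography into a frame `scale`
#' times larger, plus landmark pairs exactly related by `H_true` with
#' optional Gaussian coordinate noise added in the destination frame.
#'
#' @param cube a [hypercube()] (the HSI / destination frame).
#' @param H_true an invertible [homography()] mapping colposcope (source)
#'   coordinates to HSI (destination) coordinates.
#' @param scale colposcope-to-HSI resolution factor (>= 1).
#' @param noise_sd landmark coordinate noise sd in destination pixels.
#' @param n_landmarks number of landmark pairs (>= 4).
#' @param seed optional integer seed for landmark placement and noise.
#' @return List: `rgb` (`H x W x 3` array in the colposcope frame),
#'   `landmarks` (a [landmark_set()] colposcope -> HSI).
#' @export
generate_second_view <- function(cube, H_true, scale = 2, noise_sd = 0,
                                 n_landmarks = 6L, seed = NULL) {
  stopifnot(inherits(cube, "hypercube"), scale >= 1, n_landmarks >= 4L)
  H_true <- homography(unclass(H_true))   # validates invertibility
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- dim(cube$reflectance)
  out_h <- as.integer(round(d[1] * scale)); out_w <- as.integer(round(d[2] * scale))

  bands <- vapply(c(620, 540, 500), function(nm)
    which.min(abs(cube$grid$centers_nm - nm)), integer(1))
  xs <- rep(0:(out_w - 1L), each = out_h)
  ys <- rep(0:(out_h - 1L), times = out_w)
  hsipts <- suppressWarnings(project_points(H_true, cbind(xs, ys)))
  sx <- as.integer(round(hsipts[, 1])); sy <- as.integer(round(hsipts[, 2]))
  ok <- is.finite(hsipts[, 1]) & is.finite(hsipts[, 2]) &
        sx >= 0L & sx < d[2] & sy >= 0L & sy < d[1]
  rgb <- array(0, dim = c(out_h, out_w, 3L))
  for (b in 1:3) {
    plane <- matrix(0, out_h, out_w)
    band <- cube$reflectance[, , bands[b]]
    plane[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- band[cbind(sy[ok] + 1L, sx[ok] + 1L)]
    rgb[, , b] <- plane
  }

  # landmark destinations on a ring in the HSI frame center: guaranteed
  # non-collinear, spread over the scene
  cx <- (d[2] - 1) / 2; cy <- (d[1] - 1) / 2
  r <- 0.3 * min(d[1], d[2])
  th0 <- stats::runif(1, 0, 2 * pi)
  th <- th0 + 2 * pi * (seq_len(n_landmarks) - 1) / n_landmarks
  dst <- cbind(x = cx + r * cos(th), y = cy + r * sin(th))
  src <- project_points(solve(unclass(H_true)), dst)
  if (noise_sd > 0) {
    dst <- dst + matrix(stats::rnorm(2 * n_landmarks, sd = noise_sd),
                        ncol = 2)
  }
  list(rgb = rgb,
       landmarks = landmark_set(src, dst, source_frame = "colposcope",
                                destination_frame = "hsi"))
}
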