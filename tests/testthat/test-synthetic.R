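# Phantom generator: Beer-Lambert cube, examiner simulation, second view.

test_that("zero concentration and zero noise reproduce the baseline reflectance", {
  spec <- phantom_spec(image_height = 32, image_width = 32,
                       disc_center = c(15.5, 15.5), disc_radius = 12,
                       lesion_regions = list(list(
                         class = "major",
                         polygon = circle_polygon(15.5, 15.5, 4),
                         multipliers = c(water = 2))),
                       baseline_concentrations = c(oxyhemoglobin = 0,
                                                   deoxyhemoglobin = 0,
                                                   water = 0),
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom_cube(spec)
  inside <- which(ph$truth$masks$healthy + ph$truth$masks$major == 1L)
  flat <- matrix(ph$cube$reflectance, 32 * 32, spec$grid$n_bands)
  base <- cervhsi:::default_baseline_reflectance(spec$grid$centers_nm)
  expect_lt(max(abs(sweep(flat[inside, ], 2, base))), 1e-12)
})

test_that("identical spec and seed give bit-identical cubes", {
  spec <- phantom_spec(image_height = 32, image_width = 32,
                       disc_center = c(15.5, 15.5), disc_radius = 12,
                       lesion_regions = list(list(
                         class = "major",
                         polygon = circle_polygon(13, 13, 4),
                         multipliers = c(water = 2))),
                       seed = 9)
  a <- generate_phantom_cube(spec)
  b <- generate_phantom_cube(spec)
  expect_identical(a$cube$reflectance, b$cube$reflectance)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("reflectance stays in [0,1] and truth masks partition the disc", {
  ph <- generate_phantom_cube(phantom_spec(seed = 4))
  expect_true(all(ph$cube$reflectance >= 0 & ph$cube$reflectance <= 1))
  lesion <- pmax(ph$truth$masks$major, ph$truth$masks$minor)
  expect_true(all(lesion * ph$truth$masks$healthy == 0L))  # disjoint classes
})

test_that("phantom validation rejects bad specs", {
  expect_error(phantom_spec(lesion_regions = list(list(
    class = "major",
    polygon = circle_polygon(90, 90, 10),   # outside the disc
    multipliers = c(water = 2)))), "outside")
  expect_error(phantom_spec(noise_sd = -1))
  expect_error(phantom_spec(baseline_concentrations = c(water = -0.1)))
})

test_that("hemoglobin multiplier raises lesion absorbance in the 530-590 nm window", {
  mk <- function(mult) {
    phantom_spec(image_height = 48, image_width = 48,
                 disc_center = c(23.5, 23.5), disc_radius = 18,
                 lesion_regions = list(list(
                   class = "major",
                   polygon = circle_polygon(20, 20, 6),
                   multipliers = c(oxyhemoglobin = mult,
                                   deoxyhemoglobin = mult))),
                 noise_sd = 0, seed = 2)
  }
  win_mean <- function(ph, mask) {
    A <- absorbance(ph$cube)
    bands <- band_window(ph$cube$grid, 530, 590)
    mean(apply(A[, , bands, drop = FALSE], 3, function(sl) mean(sl[mask == 1L])))
  }
  ph2 <- generate_phantom_cube(mk(2.0))
  ph1 <- generate_phantom_cube(mk(1.0))
  les <- ph2$truth$masks$major; hea <- ph2$truth$masks$healthy
  expect_gt(win_mean(ph2, les), win_mean(ph2, hea))     # lesion > healthy
  # and with multiplier 1.0 the contrast vanishes
  expect_lt(abs(win_mean(ph1, ph1$truth$masks$major) -
                win_mean(ph1, ph1$truth$masks$healthy)), 1e-9)
})

test_that("doubling water raises TWI at every lesion pixel (noise-free)", {
  mk <- function(wmult) {
    phantom_spec(image_height = 48, image_width = 48,
                 disc_center = c(23.5, 23.5), disc_radius = 18,
                 lesion_regions = list(list(
                   class = "major",
                   polygon = circle_polygon(20, 20, 6),
                   multipliers = c(water = wmult))),
                 noise_sd = 0, seed = 2)
  }
  twi <- function(ph) compute_index(ph$cube, default_index_defs()$TWI)$values
  base <- generate_phantom_cube(mk(1.0))
  doubled <- generate_phantom_cube(mk(2.0))
  les <- which(doubled$truth$masks$major == 1L)
  expect_true(all(twi(doubled)[les] > twi(base)[les]))
})

test_that("index contrast grows with the injected multiplier (expectation over seeds)", {
  contrast <- function(mult, seed) {
    spec <- phantom_spec(image_height = 48, image_width = 48,
                         disc_center = c(23.5, 23.5), disc_radius = 18,
                         lesion_regions = list(list(
                           class = "major",
                           polygon = circle_polygon(20, 20, 6),
                           multipliers = c(water = mult))),
                         noise_sd = 0.01, seed = seed)
    ph <- generate_phantom_cube(spec)
    m <- compute_index(ph$cube, default_index_defs()$TWI)
    region_mean_index(m, ph$truth$masks$major) -
      region_mean_index(m, ph$truth$masks$healthy)
  }
  lo <- mean(sapply(1:5, function(s) contrast(1.3, s)))
  hi <- mean(sapply(1:5, function(s) contrast(2.0, s)))
  expect_gt(hi, lo)
  expect_gt(lo, 0)
})

test_that("examiner simulation is exact at zero noise and returns the requested count", {
  ph <- generate_phantom_cube(phantom_spec(seed = 5))
  ann0 <- simulate_examiner_annotations(
    ph$truth, examiner_noise_spec(n_examiners = 5, boundary_jitter_sd = 0,
                                  dilation_bias_range = 0,
                                  omission_probability = 0, seed = 1))
  expect_length(ann0, 5L)
  for (a in ann0) {
    expect_identical(a$masks$major, ph$truth$masks$major)
    expect_identical(a$masks$minor, ph$truth$masks$minor)
    expect_identical(a$masks$healthy, ph$truth$masks$healthy)
  }
  ann3 <- simulate_examiner_annotations(ph$truth,
                                        examiner_noise_spec(n_examiners = 3,
                                                            seed = 2))
  expect_length(ann3, 3L)
})

test_that("larger boundary jitter lowers mean pairwise examiner IoU", {
  ph <- generate_phantom_cube(phantom_spec(seed = 6))
  mean_iou <- function(jit, seed) {
    ann <- simulate_examiner_annotations(
      ph$truth, examiner_noise_spec(n_examiners = 3, boundary_jitter_sd = jit,
                                    dilation_bias_range = 0,
                                    omission_probability = 0, seed = seed))
    vals <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      vals <- c(vals, pairwise_iou(cin_union_mask(ann[[i]]),
                                   cin_union_mask(ann[[j]])))
    }
    mean(vals)
  }
  seeds <- 1:20
  expect_lt(mean(sapply(seeds, function(s) mean_iou(4, s))),
            mean(sapply(seeds, function(s) mean_iou(1, s))))
})

test_that("second view returns exact landmark pairs and a round-trippable homography", {
  ph <- generate_phantom_cube(phantom_spec(image_height = 32, image_width = 32,
                                           disc_center = c(15.5, 15.5),
                                           disc_radius = 12,
                                           lesion_regions = list(list(
                                             class = "major",
                                             polygon = circle_polygon(14, 14, 4),
                                             multipliers = c(water = 2))),
                                           seed = 3))
  # identity, scale 1, no noise: landmarks identical in both frames
  v0 <- generate_second_view(ph$cube, homography(diag(3)), scale = 1,
                             noise_sd = 0, n_landmarks = 4, seed = 1)
  expect_equal(v0$landmarks$src, v0$landmarks$dst)
  expect_equal(nrow(v0$landmarks$src), 4L)

  H_true <- homography(matrix(c(0.5, -0.05, 2, 0.05, 0.5, -1, 1e-4, 0, 1),
                              3, 3, byrow = TRUE))
  v <- generate_second_view(ph$cube, H_true, scale = 2, noise_sd = 0,
                            n_landmarks = 6, seed = 2)
  He <- estimate_homography(v$landmarks)
  expect_lt(max(abs(unclass(He) - unclass(H_true))), 1e-6)
  expect_equal(dim(v$rgb), c(64, 64, 3))
  expect_error(generate_second_view(ph$cube,
                                    matrix(c(1, 0, 0, 2, 0, 0, 0, 0, 1), 3, 3)),
               "singular")
})
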