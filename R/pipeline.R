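# End-to-end orchestration: landmarks -> homography -> annotation transfer ->
# consensus -> tissue indices -> paired statistics, per subject and across a
# cohort.

#' Analysis configuration
#'
#' @param tau consensus threshold in (0, 1\] (default 0.5: "at least half of
#'   the examiners"; 0.75 is the conventional sensitivity re-analysis).
#' @param index_defs named list of [band_ratio_def()]s.
#' @param absorbance_floor reflectance floor for the log transform.
#' @param sd_type z-score convention, `"population"` or `"sample"`.
#' @param B,level bootstrap repeats and CI level.
#' @param seed root seed for all randomness downstream of the data.
#' @param zero_policy Wilcoxon zero-difference policy, `"drop"` or
#'   `"pratt"`.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(tau = 0.5, index_defs = default_index_defs(),
                            absorbance_floor = 1e-4,
                            sd_type = "population",
                            B = 10000L, level = 0.95, seed = 1L,
                            zero_policy = "drop") {
  stopifnot(tau > 0, tau <= 1, B >= 100L, level > 0, level < 1)
  structure(list(tau = tau, index_defs = index_defs,
                 absorbance_floor = absorbance_floor, sd_type = sd_type,
                 B = as.integer(B), level = level, seed = as.integer(seed),
                 zero_policy = zero_policy),
            class = "analysis_config")
}

#' Generate a phantom cohort
#'
#' Builds `n_subjects` independent phantom scenes from one root seed: for
#' each subject a hypercube with ground truth, a true colposcope-to-HSI
#' homography (similarity at `1/scale` plus a mild projective component), a
#' rendered second view with noisy landmarks, and simulated examiner
#' annotations drawn in the colposcope frame. Subject geometry (lesion
#' placement and size) varies between subjects.
#'
#' @param n_subjects cohort size (default 11).
#' @param seed root integer seed.
#' @param image_size HSI scene side length in pixels.
#' @param scale colposcope-to-HSI resolution factor.
#' @param landmark_noise_sd landmark coordinate noise, destination pixels.
#' @param n_landmarks landmark pairs per subject.
#' @param examiner_noise an [examiner_noise_spec()]; its `seed` field is
#'   replaced per subject. Jitter is expressed in colposcope pixels.
#' @param noise_sd cube sensor noise sd.
#' @return List of subject entries: `subject_id`, `cube`, `truth`,
#'   `annotations` (colposcope frame), `landmarks`, `H_true`.
#' @export
make_phantom_cohort <- function(n_subjects = 11L, seed = 1L,
                                image_size = 96L, scale = 2,
                                landmark_noise_sd = 0.5, n_landmarks = 6L,
                                examiner_noise = examiner_noise_spec(),
                                noise_sd = 0.01) {
  stopifnot(n_subjects >= 1L)
  subjects <- vector("list", n_subjects)
  ctr <- (image_size - 1) / 2
  disc_r <- 0.38 * image_size
  for (s in seq_len(n_subjects)) {
    sseed <- derive_subseed(seed, 3000L + s)
    set.seed(sseed)
    # subject-specific lesion geometry inside the disc
    a1 <- stats::runif(1, 0, 2 * pi)
    a2 <- a1 + stats::runif(1, 2, 4.3)
    lesions <- list(
      list(class = "major",
           polygon = circle_polygon(ctr + 0.40 * disc_r * cos(a1),
                                    ctr + 0.40 * disc_r * sin(a1),
                                    stats::runif(1, 0.26, 0.36) * disc_r),
           multipliers = c(oxyhemoglobin = 2.0, deoxyhemoglobin = 2.0,
                           water = 1.8)),
      list(class = "minor",
           polygon = circle_polygon(ctr + 0.45 * disc_r * cos(a2),
                                    ctr + 0.45 * disc_r * sin(a2),
                                    stats::runif(1, 0.20, 0.28) * disc_r),
           multipliers = c(oxyhemoglobin = 1.5, deoxyhemoglobin = 1.5,
                           water = 1.4)))
    spec <- phantom_spec(image_height = image_size, image_width = image_size,
                         disc_center = c(ctr, ctr), disc_radius = disc_r,
                         lesion_regions = lesions, noise_sd = noise_sd,
                         seed = derive_subseed(sseed, 1L))
    ph <- generate_phantom_cube(spec)

    # true colposcope -> HSI map: rotation + downscale + translation with a
    # mild projective term
    set.seed(derive_subseed(sseed, 2L))
    th <- stats::runif(1, -0.12, 0.12)
    tx <- stats::runif(1, -3, 3); ty <- stats::runif(1, -3, 3)
    p <- stats::runif(2, -5e-5, 5e-5)
    H_true <- homography(matrix(c(
      cos(th) / scale, -sin(th) / scale, tx,
      sin(th) / scale,  cos(th) / scale, ty,
      p[1], p[2], 1), 3, 3, byrow = TRUE))

    view <- generate_second_view(ph$cube, H_true, scale = scale,
                                 noise_sd = landmark_noise_sd,
                                 n_landmarks = n_landmarks,
                                 seed = derive_subseed(sseed, 3L))
    col_shape <- c(round(image_size * scale), round(image_size * scale))
    truth_col <- transform_annotation_frame(
      ph$truth, homography(solve(unclass(H_true))), col_shape,
      frame = "colposcope")
    enoise <- examiner_noise
    enoise$seed <- derive_subseed(sseed, 4L)
    annotations <- simulate_examiner_annotations(truth_col, enoise)
    sid <- sprintf("subject_%02d", s)
    for (i in seq_along(annotations)) annotations[[i]]$subject_id <- sid
    subjects[[s]] <- list(subject_id = sid, cube = ph$cube,
                          truth = ph$truth, annotations = annotations,
                          landmarks = view$landmarks, H_true = H_true)
  }
  subjects
}

#' Process one subject through the pipeline
#'
#' Estimates the homography from the subject's landmarks, warps every
#' examiner's masks into the HSI frame, builds the union-of-CIN consensus
#' map, computes the four tissue index maps, and (at `config$tau`) derives
#' the thresholded CIN mask, the pooled healthy mask, region mean indices,
#' and region mean / z-scored spectra. Subjects whose thresholded CIN mask is
#' empty are flagged.
#'
#' @param subject a [make_phantom_cohort()] entry (or an equivalent list with
#'   `subject_id`, `cube`, `annotations`, `landmarks`).
#' @param config an [analysis_config()].
#' @return A `subject_record` list; see Details. `flagged` is TRUE when the
#'   subject cannot contribute paired values.
#' @export
run_subject <- function(subject, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  H <- estimate_homography(subject$landmarks)
  d <- dim(subject$cube$reflectance)
  hsi_shape <- d[1:2]

  warped <- lapply(subject$annotations, function(aset) {
    ms <- lapply(aset$masks, warp_mask, H = H, destination_shape = hsi_shape)
    annotation_set(ms, subject_id = aset$subject_id,
                   examiner_id = aset$examiner_id, frame = "hsi")
  })

  zero <- matrix(0L, hsi_shape[1], hsi_shape[2])
  cin_masks <- lapply(warped, function(a) {
    m <- cin_union_mask(a)
    if (is.null(m)) zero else m     # an examiner who marked nothing still counts
  })
  cmap <- consensus_map(cin_masks, class = "union")
  index_maps <- compute_all_indices(subject$cube, config$index_defs,
                                    config$absorbance_floor)

  rec <- list(subject_id = subject$subject_id, homography = H,
              residual = attr(H, "residual"), consensus = cmap,
              warped = warped, index_maps = index_maps, cube = subject$cube,
              config = config)
  rec <- c(rec, threshold_record(rec, config$tau))
  class(rec) <- "subject_record"
  rec
}

#' Re-threshold a subject record at a new consensus level
#'
#' Uses the record's stored consensus map and index maps, so sensitivity
#' re-analyses do not repeat registration or index computation.
#'
#' @param rec a `subject_record` (or the pre-threshold part of one).
#' @param tau consensus threshold.
#' @return List: `tau`, `cin_mask`, `healthy_mask`, `region_means`
#'   (data.frame index x class), `spectra` (mean and z-scored per class),
#'   `flagged`.
#' @export
threshold_record <- function(rec, tau) {
  cin_mask <- threshold_consensus(rec$consensus, tau)
  flagged <- sum(cin_mask) == 0L
  healthy_mask <- tryCatch(
    suppressWarnings(healthy_union(rec$warped, cin_mask)),
    error = function(e) NULL)
  if (is.null(healthy_mask) || sum(healthy_mask) == 0L) flagged <- TRUE
  out <- list(tau = tau, cin_mask = cin_mask, healthy_mask = healthy_mask,
              region_means = NULL, spectra = NULL, flagged = flagged)
  if (flagged) return(out)
  rm <- do.call(rbind, lapply(names(rec$index_maps), function(nm) {
    data.frame(subject_id = rec$subject_id, index = nm,
               cin_mean = region_mean_index(rec$index_maps[[nm]], cin_mask),
               healthy_mean = region_mean_index(rec$index_maps[[nm]],
                                                healthy_mask))
  }))
  sp_cin <- mean_spectrum(rec$cube, cin_mask)
  sp_h <- mean_spectrum(rec$cube, healthy_mask)
  out$region_means <- rm
  out$spectra <- list(
    cin = sp_cin, healthy = sp_h,
    cin_z = zscore_spectrum(sp_cin, rec$config$sd_type),
    healthy_z = zscore_spectrum(sp_h, rec$config$sd_type))
  out
}

#' Run the full cohort analysis
#'
#' Processes every subject, assembles the paired lesion-vs-healthy index
#' table from unflagged subjects, runs the paired nonparametric analysis,
#' and computes the examiner IoU agreement matrix on the input (colposcope
#' frame) annotations. The result is fully determined by
#' `(subjects, config)`.
#'
#' @param subjects list of subject entries (see [make_phantom_cohort()]).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, results, the paired table,
#'   and the IoU matrix are written there (see [write_cohort_outputs()]).
#' @return A `cohort_result`: `records`, `paired_table`, `stats`, `iou`,
#'   `flagged_subjects`, `config`.
#' @export
run_cohort <- function(subjects, config = analysis_config(), out_dir = NULL) {
  stopifnot(length(subjects) >= 1L)
  records <- lapply(subjects, run_subject, config = config)
  flagged <- vapply(records, function(r) isTRUE(r$flagged), logical(1))
  if (all(flagged)) {
    stop("all subjects flagged (empty consensus or healthy mask); ",
         "no paired analysis possible")
  }
  tab <- do.call(rbind, lapply(records[!flagged], `[[`, "region_means"))
  rownames(tab) <- NULL
  stats_res <- run_paired_analysis(tab, B = config$B, level = config$level,
                                   seed = config$seed,
                                   zero_policy = config$zero_policy)
  iou <- iou_matrix(lapply(subjects, `[[`, "annotations"), class = "union")
  res <- structure(
    list(records = records, paired_table = tab, stats = stats_res, iou = iou,
         flagged_subjects = vapply(records[flagged], `[[`, character(1),
                                   "subject_id"),
         config = config),
    class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_outputs(res, out_dir)
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects (%d flagged), tau = %g\n",
              length(x$records), length(x$flagged_subjects), x$config$tau))
  for (r in x$stats) print(r)
  invisible(x)
}

#' Consensus-threshold sensitivity analysis
#'
#' Repeats the paired analysis across several consensus thresholds, reusing
#' each subject's registration, consensus map and index maps.
#'
#' @param subjects list of subject entries.
#' @param config an [analysis_config()]; its `tau` is ignored.
#' @param tau_list numeric vector of thresholds.
#' @return Named list (one per tau) of lists `paired_table`, `stats`,
#'   `flagged_subjects`.
#' @export
run_sensitivity <- function(subjects, config = analysis_config(),
                            tau_list = c(0.5, 0.75)) {
  stopifnot(length(tau_list) >= 1L)
  records <- lapply(subjects, run_subject, config = config)
  out <- lapply(tau_list, function(tau) {
    th <- lapply(records, threshold_record, tau = tau)
    flagged <- vapply(th, `[[`, logical(1), "flagged")
    if (all(flagged)) {
      return(list(tau = tau, paired_table = NULL, stats = NULL,
                  flagged_subjects = vapply(records, `[[`, character(1),
                                            "subject_id")))
    }
    tab <- do.call(rbind, lapply(th[!flagged], `[[`, "region_means"))
    rownames(tab) <- NULL
    list(tau = tau,
         paired_table = tab,
         stats = run_paired_analysis(tab, B = config$B, level = config$level,
                                     seed = config$seed,
                                     zero_policy = config$zero_policy),
         flagged_subjects = vapply(records[flagged], function(r)
           r$subject_id, character(1)))
  })
  names(out) <- sprintf("tau_%g", tau_list)
  out
}
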