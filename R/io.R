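# File formats: ENVI cubes (.hdr + raw binary, BSQ/BIL/BIP), a portable
# dense-array format with a JSON sidecar, plain PGM masks and consensus maps,
# landmark CSVs, homography JSON, and cohort result files.
#
# Masks and consensus maps use portable graymaps (PGM): 8-bit 0/255 for
# binary masks, and value*n at maxval n for consensus maps, mirroring the
# usual 8/16-bit image contract without a compression dependency.

#' Write a hypercube in ENVI format
#'
#' Creates `<path_base>.hdr` (text header with the wavelength list) and
#' `<path_base>.raw` (IEEE float32, little endian) in the requested
#' interleave.
#'
#' @param cube a [hypercube()].
#' @param path_base path without extension.
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`.
#' @return `path_base`, invisibly.
#' @export
write_envi <- function(cube, path_base, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$reflectance)
  hdr <- c(
    "ENVI",
    "description = {cervhsi reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("pixel size = {%g, %g}", cube$pixel_pitch_mm, cube$pixel_pitch_mm),
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$centers_nm, trim = TRUE), collapse = ", ")))
  writeLines(hdr, paste0(path_base, ".hdr"))
  # array is [line, sample, band]; ENVI orders fastest-varying first:
  # bsq: sample, line, band / bil: sample, band, line / bip: band, sample, line
  a <- switch(interleave,
    bsq = aperm(cube$reflectance, c(2, 1, 3)),
    bil = aperm(cube$reflectance, c(2, 3, 1)),
    bip = aperm(cube$reflectance, c(3, 2, 1)))
  con <- file(paste0(path_base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(a), con, size = 4L, endian = "little")
  invisible(path_base)
}

# minimal ENVI header parser: "key = value" lines, {...} lists may span lines
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  pos <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1]]
  if (pos[1] == -1) stop("no key = value entries in ENVI header")
  for (i in seq_along(pos)) {
    chunk <- substr(txt, pos[i], pos[i] + attr(pos, "match.length")[i] - 1L)
    key <- tolower(trimws(sub("=.*$", "", chunk)))
    val <- trimws(sub("^[^=]*=", "", chunk))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI hypercube
#'
#' Supports BSQ/BIL/BIP interleaves, data types 4 (float32) and 5 (float64),
#' little/big endian, and a `wavelength` list in the header (else a
#' `wavelength_grid` must be supplied).
#'
#' @param path_base path without extension, or the `.hdr` path itself; the
#'   binary is looked up as `.raw`, `.img`, `.dat`, or `.bin`.
#' @param grid optional [build_grid()] overriding header wavelengths.
#' @param pixel_pitch_mm metadata default when absent from the header.
#' @return A [hypercube()].
#' @export
read_envi <- function(path_base, grid = NULL, pixel_pitch_mm = 0.45) {
  hdr_path <- if (grepl("\\.hdr$", path_base)) path_base
              else paste0(path_base, ".hdr")
  base <- sub("\\.hdr$", "", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  if (!all(need %in% names(h))) {
    stop("ENVI header missing: ", paste(setdiff(need, names(h)), collapse = ", "))
  }
  w <- as.integer(h$samples); hh <- as.integer(h$lines); B <- as.integer(h$bands)
  interleave <- tolower(trimws(h$interleave))
  dtype <- as.integer(h$`data type`)
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  endian <- if (!is.null(h$`byte order`) && as.integer(h$`byte order`) == 1L)
    "big" else "little"
  bin <- NULL
  for (ext in c(".raw", ".img", ".dat", ".bin", "")) {
    if (file.exists(paste0(base, ext))) { bin <- paste0(base, ext); break }
  }
  if (is.null(bin)) stop("ENVI binary file not found for ", base)
  con <- file(bin, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = w * hh * B, size = size, endian = endian)
  if (length(v) != w * hh * B) stop("ENVI binary shorter than header implies")
  a <- switch(interleave,
    bsq = aperm(array(v, dim = c(w, hh, B)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(w, B, hh)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(B, w, hh)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  if (is.null(grid)) {
    if (is.null(h$wavelength)) stop("header has no wavelength list; pass `grid`")
    wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
    if (length(wl) != B) stop("wavelength list length != bands")
    steps <- diff(wl)
    if (length(wl) > 1 && diff(range(steps)) > 1e-6) {
      stop("non-uniform wavelength grid not supported")
    }
    grid <- build_grid(wl[1], if (length(wl) > 1) steps[1] else 1, wl[B])
  }
  hypercube(a, grid, pixel_pitch_mm)
}

#' Write a hypercube as a portable dense array with JSON sidecar
#'
#' `<path_base>.bin` holds the raw float64 values (column-major
#' `H x W x B`, little endian); `<path_base>.json` records the shape,
#' wavelength grid and pixel pitch.
#'
#' @param cube a [hypercube()].
#' @param path_base path without extension.
#' @export
write_cube_array <- function(cube, path_base) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$reflectance)
  meta <- list(height = d[1], width = d[2], bands = d[3],
               dtype = "float64", order = "column-major",
               byte_order = "little",
               wavelength_start_nm = cube$grid$start_nm,
               wavelength_step_nm = cube$grid$step_nm,
               pixel_pitch_mm = cube$pixel_pitch_mm)
  jsonlite::write_json(meta, paste0(path_base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path_base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$reflectance), con, size = 8L, endian = "little")
  invisible(path_base)
}

#' @rdname write_cube_array
#' @export
read_cube_array <- function(path_base) {
  meta <- jsonlite::read_json(paste0(path_base, ".json"), simplifyVector = TRUE)
  n <- meta$height * meta$width * meta$bands
  con <- file(paste0(path_base, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(v) != n) stop("array file shorter than sidecar implies")
  grid <- build_grid(meta$wavelength_start_nm, meta$wavelength_step_nm,
                     meta$wavelength_start_nm +
                       meta$wavelength_step_nm * (meta$bands - 1))
  hypercube(array(v, dim = c(meta$height, meta$width, meta$bands)), grid,
            meta$pixel_pitch_mm)
}

#' Write / read a binary mask as plain PGM (P2)
#'
#' Set pixels are written as 255, clear as 0.
#'
#' @param mask binary matrix.
#' @param path output path (conventionally `.pgm`).
#' @export
write_mask_pgm <- function(mask, path) {
  mask <- as_binary_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "255"), con)
  write(t(mask) * 255L, con, ncolumns = ncol(mask))
  invisible(path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  as_binary_mask(m)
}

#' Write a consensus map as plain PGM plus JSON metadata
#'
#' Pixel values are the examiner counts (`value * n_examiners`), with
#' `maxval = n_examiners`; the sidecar records class and examiner count.
#'
#' @param map a [consensus_map()].
#' @param path_base path without extension.
#' @export
write_consensus_pgm <- function(map, path_base) {
  stopifnot(inherits(map, "consensus_map"))
  counts <- round(map$values * map$n_examiners)
  con <- file(paste0(path_base, ".pgm"), "w")
  writeLines(c("P2", sprintf("%d %d", ncol(counts), nrow(counts)),
               sprintf("%d", map$n_examiners)), con)
  write(t(counts), con, ncolumns = ncol(counts))
  close(con)
  jsonlite::write_json(
    list(class = map$class, n_examiners = map$n_examiners,
         encoding = "pixel value = number of examiners marking the pixel"),
    paste0(path_base, ".json"), auto_unbox = TRUE)
  invisible(path_base)
}

#' Write / read landmark pairs as CSV
#'
#' Columns `src_x, src_y, dst_x, dst_y` in 0-based pixel coordinates.
#'
#' @param landmarks a [landmark_set()].
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(src_x = landmarks$src[, 1], src_y = landmarks$src[, 2],
                   dst_x = landmarks$dst[, 1], dst_y = landmarks$dst[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @param source_frame,destination_frame labels for the loaded set.
#' @export
read_landmarks_csv <- function(path, source_frame = "colposcope",
                               destination_frame = "hsi") {
  df <- utils::read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  }
  landmark_set(cbind(df$src_x, df$src_y), cbind(df$dst_x, df$dst_y),
               source_frame, destination_frame)
}

#' Write / read a homography as JSON
#'
#' Stored as 9 numbers row-major plus the normalization tag.
#'
#' @param H a [homography()].
#' @param path JSON path.
#' @export
write_homography_json <- function(H, path) {
  stopifnot(inherits(H, "homography"))
  jsonlite::write_json(
    list(h = as.vector(t(unclass(H))), order = "row-major",
         normalization = attr(H, "normalization"),
         residual = attr(H, "residual")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_homography_json
#' @export
read_homography_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  homography(matrix(obj$h, 3, 3, byrow = TRUE))
}

# flatten one paired_stat_result into plain lists for JSON/CSV
stat_result_fields <- function(r) {
  if (!is.null(r$error)) {
    list(index = r$index_name, n = r$n, error = r$error)
  } else {
    list(index = r$index_name, n = r$n, W = r$W, p_value = r$p_value,
         hl_estimate = r$hl_estimate, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
         effect_size_r = r$effect_size_r, B = r$B, seed = r$seed)
  }
}

#' Write cohort analysis outputs
#'
#' Writes `results.json` (stats per index, config echo, flagged subjects),
#' `paired_table.csv` (figure-ready paired index data), `iou_matrix.csv`,
#' and per-subject consensus maps under `consensus/`. Deterministic: a rerun
#' from the same inputs is byte-identical.
#'
#' @param res a `cohort_result` from [run_cohort()].
#' @param out_dir output directory (created if needed).
#' @export
write_cohort_outputs <- function(res, out_dir) {
  stopifnot(inherits(res, "cohort_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  jsonlite::write_json(
    list(stats = lapply(unname(res$stats), stat_result_fields),
         flagged_subjects = res$flagged_subjects,
         config = list(tau = cfg$tau, B = cfg$B, level = cfg$level,
                       seed = cfg$seed, zero_policy = cfg$zero_policy,
                       absorbance_floor = cfg$absorbance_floor)),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$paired_table, file.path(out_dir, "paired_table.csv"),
                   row.names = FALSE)
  iou_df <- as.data.frame(res$iou$values)
  iou_df <- cbind(examiner = rownames(res$iou$values), iou_df)
  utils::write.csv(iou_df, file.path(out_dir, "iou_matrix.csv"),
                   row.names = FALSE)
  cdir <- file.path(out_dir, "consensus")
  dir.create(cdir, showWarnings = FALSE)
  for (rec in res$records) {
    write_consensus_pgm(rec$consensus, file.path(cdir, rec$subject_id))
  }
  invisible(out_dir)
}

#' Write / read a paired index table as CSV
#'
#' Long format: `subject_id, index, cin_mean, healthy_mean`.
#'
#' @param table the paired table data.frame.
#' @param path CSV path.
#' @export
write_paired_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paired_table_csv
#' @export
read_paired_table_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "index", "cin_mean", "healthy_mean")
  if (!all(need %in% names(df))) {
    stop("paired table CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}
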