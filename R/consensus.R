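# Multi-examiner annotation agreement and consensus reference masks.
#
# Examiners independently outline regions with major and minor tissue changes
# plus a healthy reference patch. Agreement is summarized per pixel (consensus
# map) and per examiner pair (IoU); the analysis mask keeps only pixels where
# consensus reaches a threshold, while healthy annotations are pooled in full
# because examiners mark only a representative healthy sample.

ANNOT_CLASSES <- c("major", "minor", "healthy")

#' Bundle one examiner's masks for one subject
#'
#' @param masks named list of binary (logical or 0/1) matrices, names among
#'   `"major"`, `"minor"`, `"healthy"`; classes the examiner did not mark may
#'   be absent. All masks must share one shape.
#' @param subject_id,examiner_id labels.
#' @param frame label of the image domain the masks live in (e.g.
#'   `"colposcope"` or `"hsi"`).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(masks, subject_id = "s1", examiner_id = "e1",
                           frame = "colposcope") {
  stopifnot(is.list(masks))
  bad <- setdiff(names(masks), ANNOT_CLASSES)
  if (length(bad)) stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  masks <- lapply(masks, as_binary_mask)
  shapes <- unique(lapply(masks, dim))
  if (length(shapes) > 1L) stop("all masks in an annotation set must share one shape")
  structure(list(subject_id = subject_id, examiner_id = examiner_id,
                 masks = masks, frame = frame),
            class = "annotation_set")
}

# Coerce to a 0/1 integer matrix; anything nonzero counts as marked.
as_binary_mask <- function(m) {
  stopifnot(is.matrix(m) || (is.array(m) && length(dim(m)) == 2L))
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

#' Union of an examiner's lesion (CIN) masks, irrespective of degree
#'
#' @param aset an [annotation_set()].
#' @return A binary matrix, or `NULL` when the examiner marked neither class.
#' @export
cin_union_mask <- function(aset) {
  stopifnot(inherits(aset, "annotation_set"))
  ms <- aset$masks[intersect(c("major", "minor"), names(aset$masks))]
  if (length(ms) == 0L) return(NULL)
  Reduce(function(a, b) pmax(a, b), ms)
}

#' Per-pixel examiner consensus map
#'
#' Normalized 2D histogram of binary annotations: each pixel's value is the
#' fraction of examiners who marked it, from 0 (nobody) to 1 (everybody).
#'
#' @param masks list of binary matrices with identical shapes, one per
#'   examiner.
#' @param class label carried in the result (`"major"`, `"minor"`, `"union"`,
#'   ...).
#' @return A `consensus_map` object with fields `values` (matrix in \[0,1\]),
#'   `class`, `n_examiners`.
#' @export
consensus_map <- function(masks, class = "union") {
  stopifnot(is.list(masks), length(masks) >= 1L)
  masks <- lapply(masks, as_binary_mask)
  shapes <- unique(lapply(masks, dim))
  if (length(shapes) > 1L) stop("masks must share one shape")
  n <- length(masks)
  acc <- Reduce(`+`, masks)
  structure(list(values = acc / n, class = class, n_examiners = n),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> class=%s, %d examiners, %d x %d px\n",
              x$class, x$n_examiners, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pairwise intersection over union (Jaccard index)
#'
#' @param a,b binary matrices of identical shape.
#' @return `|a n b| / |a u b|` in \[0, 1\]; `NA` when the union is empty
#'   (undefined, never 0 -- a 0 would conflate "both empty" with "disjoint").
#' @export
pairwise_iou <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  uni <- sum(a | b)
  if (uni == 0L) return(NA_real_)
  sum(a & b) / uni
}

#' Examiner-pair IoU matrix averaged across subjects
#'
#' Entry (i, j) is the arithmetic mean, over subjects where both examiners i
#' and j produced a defined IoU for `class`, of their pairwise IoU. Pairs with
#' an empty union on a subject are excluded from that subject's average
#' (undefined), and the diagonal is `NA` by convention.
#'
#' @param annotations list of subjects; each subject is a list of
#'   [annotation_set()]s (one per examiner, identified by `examiner_id`), all
#'   in a common frame.
#' @param class `"major"`, `"minor"`, `"healthy"`, or `"union"` (union of
#'   major and minor).
#' @return An `iou_matrix` object: `values` (E x E symmetric, `NA` diagonal),
#'   `class`, `n_pairs` (matrix of subject counts per entry).
#' @export
iou_matrix <- function(annotations, class = "union") {
  stopifnot(is.list(annotations), length(annotations) >= 1L)
  examiners <- unique(unlist(lapply(annotations, function(subj)
    vapply(subj, function(a) a$examiner_id, character(1)))))
  E <- length(examiners)
  if (E < 2L) stop("need at least 2 examiners")
  vals <- matrix(NA_real_, E, E, dimnames = list(examiners, examiners))
  npair <- matrix(0L, E, E, dimnames = list(examiners, examiners))
  get_mask <- function(aset) {
    if (class == "union") cin_union_mask(aset) else aset$masks[[class]]
  }
  for (i in seq_len(E - 1L)) for (j in (i + 1L):E) {
    ious <- c()
    for (subj in annotations) {
      ids <- vapply(subj, function(a) a$examiner_id, character(1))
      ai <- subj[[match(examiners[i], ids)]]; aj <- subj[[match(examiners[j], ids)]]
      if (is.null(ai) || is.null(aj)) next
      mi <- get_mask(ai); mj <- get_mask(aj)
      if (is.null(mi) || is.null(mj)) next
      v <- pairwise_iou(mi, mj)
      if (!is.na(v)) ious <- c(ious, v)
    }
    if (length(ious)) {
      vals[i, j] <- vals[j, i] <- mean(ious)
      npair[i, j] <- npair[j, i] <- length(ious)
    }
  }
  structure(list(values = vals, class = class, n_pairs = npair),
            class = "iou_matrix")
}

#' Threshold a consensus map into a reference mask
#'
#' Keeps pixels where the examiner-consensus fraction is at least `tau`
#' (inclusive: tau = 0.5 with 5 examiners keeps pixels marked by >= 3, i.e.
#' "at least half"). Intended for the CIN classes only; healthy annotations
#' are pooled with [healthy_union()] instead.
#'
#' @param map a [consensus_map()].
#' @param tau consensus threshold in (0, 1\].
#' @return A binary matrix.
#' @export
threshold_consensus <- function(map, tau = 0.5) {
  stopifnot(inherits(map, "consensus_map"), tau > 0, tau <= 1)
  # tolerance absorbs k/n float representation at the lattice points
  (map$values >= tau - 1e-12) * 1L
}

#' Pooled healthy reference mask
#'
#' Union of every examiner's healthy annotation, taken in its entirety
#' (examiners mark only a representative healthy patch, so no consensus
#' threshold applies), minus any pixel already in the thresholded CIN mask so
#' the two tissue classes stay disjoint.
#'
#' @param asets list of [annotation_set()]s for one subject.
#' @param cin_mask optional binary matrix to subtract (the thresholded CIN
#'   consensus mask).
#' @return A binary matrix; warns when the result is empty.
#' @export
healthy_union <- function(asets, cin_mask = NULL) {
  stopifnot(is.list(asets), length(asets) >= 1L)
  hs <- lapply(asets, function(a) a$masks[["healthy"]])
  hs <- hs[!vapply(hs, is.null, logical(1))]
  if (length(hs) == 0L) stop("no examiner marked a healthy region")
  out <- Reduce(function(a, b) pmax(a, b), lapply(hs, as_binary_mask))
  if (!is.null(cin_mask)) {
    cin_mask <- as_binary_mask(cin_mask)
    if (!identical(dim(cin_mask), dim(out))) stop("cin_mask shape differs")
    out <- out * (1L - cin_mask)
  }
  if (sum(out) == 0L) warning("healthy reference mask is empty")
  out
}
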