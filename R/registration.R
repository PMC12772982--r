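# Landmark-based projective registration between the colposcope frame and the
# hyperspectral frame.
#
# A 3x3 homography H maps source-image pixel coordinates to destination-image
# coordinates, [x', y', 1]^T ~ H [x, y, 1]^T. H is estimated from >= 4
# expert-marked landmark pairs by minimizing the back-projection error
#   sum_i (x'_i - (h11 x_i + h12 y_i + h13)/(h31 x_i + h32 y_i + h33))^2
#       + (y'_i - (h21 x_i + h22 y_i + h23)/(h31 x_i + h32 y_i + h33))^2 .
#
# Pixel coordinate convention throughout: 0-based, x = column index,
# y = row index, pixel centers at integer coordinates.

#' Landmark correspondence set
#'
#' @param src,dst n x 2 numeric matrices of (x, y) pixel coordinates in the
#'   source and destination frames; row i of `src` corresponds to row i of
#'   `dst`.
#' @param source_frame,destination_frame labels.
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(src, dst, source_frame = "colposcope",
                         destination_frame = "hsi") {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst),
            is.numeric(src), is.numeric(dst),
            all(is.finite(src)), all(is.finite(dst)))
  colnames(src) <- colnames(dst) <- c("x", "y")
  structure(list(src = src, dst = dst, source_frame = source_frame,
                 destination_frame = destination_frame),
            class = "landmark_set")
}

#' Wrap a 3x3 matrix as a homography
#'
#' Normalizes so that `h[3,3] = 1` when that entry is well away from zero,
#' otherwise to unit Frobenius norm.
#'
#' @param h numeric 3x3 matrix with nonzero determinant.
#' @return A `homography` object (the normalized matrix, with a
#'   `normalization` attribute).
#' @export
homography <- function(h) {
  h <- as.matrix(h)
  stopifnot(identical(dim(h), c(3L, 3L)), all(is.finite(h)))
  if (abs(det(h)) < 1e-14 * max(abs(h))^3) stop("homography matrix is singular")
  if (abs(h[3, 3]) > 1e-8 * sqrt(sum(h^2))) {
    h <- h / h[3, 3]
    norm_tag <- "h33"
  } else {
    h <- h / sqrt(sum(h^2))
    norm_tag <- "frobenius"
  }
  structure(h, class = "homography", normalization = norm_tag)
}

#' Apply a homography to points
#'
#' Homogeneous multiplication followed by perspective division.
#'
#' @param H a [homography()] (or plain 3x3 matrix).
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates. Points whose homogeneous
#'   w-coordinate vanishes map to `Inf` and trigger a warning.
#' @export
project_points <- function(H, points) {
  H <- unclass(H)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  ph <- cbind(points, 1) %*% t(H)
  w <- ph[, 3]
  if (any(abs(w) < 1e-12)) warning("point(s) mapped to infinity (w ~ 0)")
  cbind(x = ph[, 1] / w, y = ph[, 2] / w)
}

#' Back-projection error of a homography on landmarks
#'
#' The exact least-squares objective of the estimation: total squared residual
#' between projected source landmarks and their destination positions.
#'
#' @param H a [homography()] or 3x3 matrix.
#' @param landmarks a [landmark_set()].
#' @return Nonnegative scalar (squared pixels); 0 iff every pair maps exactly.
#' @export
backprojection_error <- function(H, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  proj <- project_points(H, landmarks$src)
  if (any(!is.finite(proj))) {
    warning("back-projection error is infinite (point at infinity)")
    return(Inf)
  }
  sum((proj - landmarks$dst)^2)
}

# Hartley normalization: translate centroid to the origin and scale so the
# mean distance from it is sqrt(2). Returns the 3x3 similarity transform.
normalization_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

# TRUE when pts contains three (near-)collinear points among exactly four, or
# when fewer than two points lie off a common line.
degenerate_configuration <- function(pts, tol = 1e-8) {
  n <- nrow(pts)
  scale <- max(1, max(abs(pts)))
  if (n == 4L) {
    combs <- utils::combn(n, 3L)
    for (k in seq_len(ncol(combs))) {
      p <- pts[combs[, k], , drop = FALSE]
      cross <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
      if (abs(cross) < tol * scale^2) return(TRUE)
    }
    return(FALSE)
  }
  # general case: all points on one line leaves H underdetermined
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  sv[2] < tol * max(sv[1], scale)
}

#' Estimate a homography from landmark correspondences
#'
#' Normalized (Hartley) direct linear transform solved by SVD, followed by
#' Levenberg-style refinement of the 8 free parameters against the
#' back-projection error. With four pairs in general position the solution is
#' exact and unique; with more pairs it is the least-squares minimizer. All
#' pairs are used (landmarks are few and hand-curated; no robust rejection).
#'
#' @param landmarks a [landmark_set()] with at least 4 pairs; no three source
#'   points may be collinear.
#' @param refine logical; run the nonlinear refinement (default TRUE).
#' @return A [homography()] with attributes `residual` (back-projection error
#'   at the optimum) and `n_landmarks`.
#' @export
estimate_homography <- function(landmarks, refine = TRUE) {
  stopifnot(inherits(landmarks, "landmark_set"))
  n <- nrow(landmarks$src)
  if (n < 4L) stop("homography estimation requires at least 4 landmark pairs")
  if (degenerate_configuration(landmarks$src) ||
      degenerate_configuration(landmarks$dst)) {
    stop("degenerate landmark configuration (collinear points); ",
         "a unique homography requires 4 pairs in general position")
  }
  Ts <- normalization_transform(landmarks$src)
  Td <- normalization_transform(landmarks$dst)
  sp <- project_points(Ts, landmarks$src)
  dp <- project_points(Td, landmarks$dst)

  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- sp[i, 1]; y <- sp[i, 2]; xp <- dp[i, 1]; yp <- dp[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, xp * x, xp * y, xp)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, yp * x, yp * y, yp)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1]) {
    stop("degenerate landmark configuration: homography not unique")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  H <- homography(H)

  if (refine && abs(H[3, 3]) > 0) {
    # 8-parameter minimization of the printed objective, h33 fixed at 1
    par0 <- as.vector(t(unclass(H)))[1:8]
    obj <- function(p) {
      Hm <- matrix(c(p, 1), 3, 3, byrow = TRUE)
      pr <- tryCatch(project_points(Hm, landmarks$src),
                     warning = function(w) NULL)
      if (is.null(pr) || any(!is.finite(pr))) return(1e18)
      sum((pr - landmarks$dst)^2)
    }
    fit <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
    if (is.finite(fit$value) && fit$value <= obj(par0)) {
      H <- homography(matrix(c(fit$par, 1), 3, 3, byrow = TRUE))
    }
  }
  attr(H, "residual") <- backprojection_error(H, landmarks)
  attr(H, "n_landmarks") <- n
  H
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> (", attr(x, "normalization"), "-normalized)\n", sep = "")
  print(unclass(x)[1:3, 1:3])
  if (!is.null(attr(x, "residual"))) {
    cat(sprintf("back-projection residual: %.6g px^2 on %d landmarks\n",
                attr(x, "residual"), attr(x, "n_landmarks")))
  }
  invisible(x)
}

#' Warp a binary mask through a homography
#'
#' Inverse nearest-neighbor mapping: a destination pixel is set iff its
#' center, mapped through `H^-1`, rounds to a set source pixel. Masks stay
#' strictly binary; destination pixels that map outside the source extent are
#' 0.
#'
#' @param H a [homography()] mapping source coordinates to destination
#'   coordinates.
#' @param mask binary source matrix (rows = y, cols = x).
#' @param destination_shape integer `c(H, W)` of the output.
#' @return Binary matrix of shape `destination_shape`.
#' @export
warp_mask <- function(H, mask, destination_shape) {
  mask <- as_binary_mask(mask)
  stopifnot(length(destination_shape) == 2L, all(destination_shape >= 1))
  Hinv <- solve(unclass(H))
  dh <- as.integer(destination_shape[1]); dw <- as.integer(destination_shape[2])
  # destination pixel centers, 0-based (x = col, y = row)
  xs <- rep(0:(dw - 1L), each = dh)
  ys <- rep(0:(dh - 1L), times = dw)
  srcpts <- suppressWarnings(project_points(Hinv, cbind(xs, ys)))
  sx <- as.integer(round(srcpts[, 1])); sy <- as.integer(round(srcpts[, 2]))
  ok <- is.finite(srcpts[, 1]) & is.finite(srcpts[, 2]) &
        sx >= 0L & sx < ncol(mask) & sy >= 0L & sy < nrow(mask)
  out <- integer(dh * dw)
  out[ok] <- mask[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  matrix(out, dh, dw)
}
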