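# Shared low-level helpers: seeded stream splitting and polygon rasterization.

#' Derive a reproducible sub-seed from a root seed
#'
#' One root seed is expanded into independent per-component streams by a fixed
#' affine congruential rule, so the phantom generator, examiner simulator and
#' bootstrap never share a stream. Result always lies in \[1, 2^31 - 2\].
#'
#' @param seed integer root seed.
#' @param k integer stream index.
#' @return Integer sub-seed.
#' @export
derive_subseed <- function(seed, k) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) * 69621 + (abs(as.double(k)) %% m) * 1013904223
  as.integer(s %% (m - 1)) + 1L
}

#' Closed polygon approximating a circle
#'
#' @param cx,cy center in pixel coordinates (0-based, x = column, y = row).
#' @param r radius in pixels.
#' @param n_vertices number of vertices.
#' @return n x 2 matrix of (x, y) vertices.
#' @export
circle_polygon <- function(cx, cy, r, n_vertices = 72L) {
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Rasterize a polygon onto a pixel grid
#'
#' Even-odd rule; a pixel is included iff its center (integer coordinates,
#' 0-based) lies inside the polygon. Deterministic and resolution-stable.
#'
#' @param poly n x 2 matrix of (x, y) vertices (closed implicitly).
#' @param shape integer `c(H, W)`.
#' @return Binary `H x W` matrix.
#' @export
rasterize_polygon <- function(poly, shape) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2L, nrow(poly) >= 3L, length(shape) == 2L)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  out <- matrix(0L, h, w)
  # bounding box confines the scan
  x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(w - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(h - 1L, ceiling(max(poly[, 2])))
  if (x0 > x1 || y0 > y1) return(out)
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  out[cbind(py + 1L, px + 1L)] <- as.integer(inside)
  out
}

# mean-of-vertices centroid; adequate for the star-shaped regions used here
polygon_centroid <- function(poly) colMeans(poly)

#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)
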