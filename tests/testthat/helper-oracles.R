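# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (explicit loops, full enumeration) so they never share a
# code path with the implementation they check.

# pixel-counting IoU: explicit double loop
oracle_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    ai <- a[i, j] != 0; bi <- b[i, j] != 0
    if (ai && bi) inter <- inter + 1L
    if (ai || bi) uni <- uni + 1L
  }
  if (uni == 0L) NA_real_ else inter / uni
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (midranks for ties)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  stopifnot(n <= 16)
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(pmin(w_all, total - w_all) <= w_obs)
}

# Hodges-Lehmann by explicit Walsh-average loops
oracle_hl <- function(d) {
  n <- length(d)
  w <- c()
  for (i in seq_len(n)) for (j in i:n) w <- c(w, (d[i] + d[j]) / 2)
  median(w)
}

# back-projection error recomputed point by point from the printed formula
oracle_backprojection <- function(H, src, dst) {
  H <- unclass(H)
  tot <- 0
  for (i in seq_len(nrow(src))) {
    den <- H[3, 1] * src[i, 1] + H[3, 2] * src[i, 2] + H[3, 3]
    px <- (H[1, 1] * src[i, 1] + H[1, 2] * src[i, 2] + H[1, 3]) / den
    py <- (H[2, 1] * src[i, 1] + H[2, 2] * src[i, 2] + H[2, 3]) / den
    tot <- tot + (dst[i, 1] - px)^2 + (dst[i, 2] - py)^2
  }
  unname(tot)
}

# per-band mean over masked pixels by explicit loops
oracle_mean_spectrum <- function(cube, mask) {
  d <- dim(cube$reflectance)
  out <- numeric(d[3])
  for (b in seq_len(d[3])) {
    acc <- 0; cnt <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (mask[i, j] != 0) { acc <- acc + cube$reflectance[i, j, b]; cnt <- cnt + 1 }
    }
    out[b] <- acc / cnt
  }
  out
}

# random binary mask with given fill probability
random_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# tiny cube with constant or per-band values
tiny_cube <- function(h = 4, w = 4, grid = build_grid(600, 100, 800),
                     value = 0.5) {
  B <- grid$n_bands
  if (length(value) == 1L) value <- rep(value, B)
  a <- array(rep(value, each = h * w), dim = c(h, w, B))
  hypercube(a, grid)
}

# random well-conditioned projective transform (mild perspective terms)
random_homography <- function() {
  th <- runif(1, -0.5, 0.5); s <- runif(1, 0.6, 1.6)
  homography(matrix(c(
    s * cos(th), -s * sin(th), runif(1, -20, 20),
    s * sin(th),  s * cos(th), runif(1, -20, 20),
    runif(1, -2e-4, 2e-4), runif(1, -2e-4, 2e-4), 1), 3, 3, byrow = TRUE))
}

# small, fast phantom defaults for pipeline tests
small_cohort <- function(n = 3, seed = 1, image_size = 48L) {
  make_phantom_cohort(n_subjects = n, seed = seed, image_size = image_size)
}
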