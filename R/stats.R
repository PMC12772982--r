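# Paired nonparametric inference for lesion vs healthy tissue indices.
#
# One paired sample per subject and index. The test is the Wilcoxon
# signed-rank test (two-sided); the effect estimate is the Hodges-Lehmann
# pseudo-median of the paired differences with a percentile bootstrap CI, and
# a standardized effect size r = |Z| / sqrt(n) is reported alongside.

#' Wilcoxon signed-rank test for paired samples
#'
#' Ranks the absolute nonzero differences (midranks for ties) and reports
#' `W`, the smaller of the positive and negative rank sums. With at most
#' `exact_max_n` nonzero differences the two-sided p-value comes from the
#' exact null distribution of the rank sum over all `2^n` equally likely
#' sign assignments (enumerated by convolution, ties included); for larger
#' samples the normal approximation with tie correction and a 0.5 continuity
#' correction is used.
#'
#' @param x,y equal-length paired numeric vectors (the test uses `x - y`).
#' @param zero_policy `"drop"` (Wilcoxon's original policy: discard zero
#'   differences before ranking; default) or `"pratt"` (rank zeros with the
#'   rest, then discard their ranks).
#' @param mode `"auto"` (exact when admissible), `"exact"`, or `"approx"`.
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @return List: `W`, `p_value`, `z` (tie-corrected normal deviate of the
#'   positive rank sum, reported in every mode), `n_used` (nonzero
#'   differences), `method`. Errors when every difference is zero.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_policy = c("drop", "pratt"),
                                 mode = c("auto", "exact", "approx"),
                                 exact_max_n = 25L) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 1L)
  d <- x - y
  d <- d[is.finite(d)]
  if (all(d == 0)) stop("all paired differences are zero; test undefined")

  if (zero_policy == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))      # zeros participate in ranking...
    r <- r[d != 0]         # ...but their ranks are discarded
    d <- d[d != 0]
  }
  n <- length(d)
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)

  ties <- any(duplicated(r))
  # tie-corrected normal deviate of the positive rank sum (always reported;
  # it also feeds the standardized effect size r = |Z|/sqrt(n))
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  cc <- sign(w_pos - mu) * 0.5
  z <- if (sigma > 0) (w_pos - mu - cc) / sigma else 0

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n <= exact_max_n)
  if (use_exact && n > 30L) {
    stop("exact mode is limited to n <= 30 nonzero differences")
  }
  if (use_exact) {
    # exact null distribution of the positive rank sum over all 2^n equally
    # likely sign assignments, computed by shift-convolution on doubled
    # (mid)ranks -- identical to literal enumeration, polynomial time
    r2 <- as.integer(round(2 * r))
    T2 <- sum(r2)
    cnt <- numeric(T2 + 1)
    cnt[1] <- 1
    for (wt in r2) {
      cnt <- cnt + c(numeric(wt), cnt[seq_len(T2 + 1 - wt)])
    }
    wvals <- 0:T2
    W2 <- as.integer(round(2 * W))
    p <- sum(cnt[pmin(wvals, T2 - wvals) <= W2]) / 2^n
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie and continuity corrected)"
  }
  list(W = W, p_value = min(1, p), z = z, n_used = n, method = method)
}

#' Hodges-Lehmann estimate of the paired shift
#'
#' Median of all `n(n+1)/2` Walsh averages `(d_i + d_j)/2`, `i <= j`, of the
#' paired differences: a robust pseudo-median of the typical within-pair
#' change.
#'
#' @param diffs numeric vector of paired differences (length >= 1).
#' @return Scalar estimate.
#' @export
hodges_lehmann <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1L)
  stats::median(walsh_averages(diffs))
}

# all (d_i + d_j)/2 for i <= j, self-pairs included
walsh_averages <- function(d) {
  s <- outer(d, d, `+`) / 2
  s[upper.tri(s, diag = TRUE)]
}

#' Percentile bootstrap confidence interval for a statistic of paired
#' differences
#'
#' Resamples the differences with replacement `B` times, evaluates
#' `statistic` on each resample, and returns the central `level` percentile
#' interval. Fully determined by `seed`.
#'
#' @param diffs numeric vector of paired differences.
#' @param statistic function of a numeric vector (default [hodges_lehmann()]).
#' @param B number of bootstrap resamples (>= 100; default 10000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Length-2 vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(diffs, statistic = hodges_lehmann, B = 10000L,
                         level = 0.95, seed = NULL) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1L, B >= 100L,
            level > 0, level < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(diffs)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  if (identical(statistic, hodges_lehmann)) {
    stat <- bootstrap_hl_rows(matrix(diffs[idx], B, n))
  } else {
    stat <- apply(idx, 1L, function(i) statistic(diffs[i]))
  }
  a <- (1 - level) / 2
  unname(stats::quantile(stat, c(a, 1 - a), type = 7))
}

# vectorized Hodges-Lehmann over the rows of a B x n matrix: builds the
# n(n+1)/2 Walsh-average columns once, then takes row medians
bootstrap_hl_rows <- function(X) {
  n <- ncol(X)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  W <- (X[, pairs[, 1], drop = FALSE] + X[, pairs[, 2], drop = FALSE]) / 2
  m <- ncol(W)
  half <- m %/% 2L
  if (m %% 2L == 1L) {
    apply(W, 1L, function(v) sort(v, partial = half + 1L)[half + 1L])
  } else {
    apply(W, 1L, function(v) {
      v <- sort(v, partial = c(half, half + 1L)); (v[half] + v[half + 1L]) / 2
    })
  }
}

#' Standardized effect size r
#'
#' `r = |Z| / sqrt(n)` with `Z` the (tie-corrected) normal-approximation
#' deviate of the signed-rank statistic, clipped to \[0, 1\].
#'
#' @param z normal deviate of the test statistic.
#' @param n number of pairs used in the test.
#' @return Scalar in \[0, 1\].
#' @export
effect_size_r <- function(z, n) {
  stopifnot(is.numeric(z), length(z) == 1L, n >= 1)
  min(1, abs(z) / sqrt(n))
}

#' Paired lesion-vs-healthy analysis across all tissue indices
#'
#' For each index column pair the differences are oriented lesion (CIN) minus
#' healthy; the signed-rank test, Hodges-Lehmann estimate, bootstrap CI, and
#' effect size r are computed. Raw p-values are reported without multiplicity
#' adjustment. Indices whose differences are all zero are flagged
#' (`error` field) rather than tested.
#'
#' @param table data.frame with columns `subject_id`, `index`, `cin_mean`,
#'   `healthy_mean` (long format, one row per subject x index).
#' @param B,level,seed,zero_policy passed to [bootstrap_ci()] and
#'   [wilcoxon_signed_rank()]; each index's bootstrap gets a sub-seed derived
#'   from `seed`.
#' @return List of per-index result lists (class `paired_stat_result`):
#'   `index_name`, `n`, `W`, `p_value`, `hl_estimate`, `ci95`,
#'   `effect_size_r`, `B`, `seed`, or `error` when untestable.
#' @export
run_paired_analysis <- function(table, B = 10000L, level = 0.95, seed = 1L,
                                zero_policy = "drop") {
  need <- c("subject_id", "index", "cin_mean", "healthy_mean")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  idxs <- unique(as.character(table$index))
  out <- vector("list", length(idxs))
  names(out) <- idxs
  for (k in seq_along(idxs)) {
    sub <- table[table$index == idxs[k], , drop = FALSE]
    d <- sub$cin_mean - sub$healthy_mean
    res <- list(index_name = idxs[k], n = length(d))
    if (all(d == 0)) {
      res$error <- "all paired differences are zero"
    } else {
      wt <- wilcoxon_signed_rank(sub$cin_mean, sub$healthy_mean,
                                 zero_policy = zero_policy)
      res$W <- wt$W
      res$p_value <- wt$p_value
      res$n <- wt$n_used
      res$hl_estimate <- hodges_lehmann(d)
      res$ci95 <- bootstrap_ci(d, B = B, level = level,
                               seed = derive_subseed(seed, k))
      res$effect_size_r <- effect_size_r(wt$z, wt$n_used)
      res$B <- B
      res$seed <- seed
    }
    class(res) <- "paired_stat_result"
    out[[k]] <- res
  }
  out
}

#' @export
print.paired_stat_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("%s: not testable (%s), n=%d\n", x$index_name, x$error, x$n))
  } else {
    cat(sprintf(
      "%s: n=%d, W=%g, p=%.4g, HL=%.4f, 95%% CI [%.4f, %.4f], r=%.2f\n",
      x$index_name, x$n, x$W, x$p_value, x$hl_estimate,
      x$ci95[1], x$ci95[2], x$effect_size_r))
  }
  invisible(x)
}
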