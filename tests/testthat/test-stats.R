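test_that("signed-rank test: constant positive shift gives W = 0 and the minimal p", {
  y <- (1:11) / 10
  res <- wilcoxon_signed_rank(y + 0.5, y)
  expect_equal(res$W, 0)
  expect_equal(res$p_value, 2 / 2^11)   # 0.000977: both extreme sign patterns
  expect_equal(res$n_used, 11L)
  expect_equal(res$method, "exact")
})

test_that("perfectly balanced differences give p = 1", {
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  res <- wilcoxon_signed_rank(d, rep(0, 8), mode = "approx")
  expect_equal(res$p_value, 1)
  expect_equal(res$z, 0)
})

test_that("exact p matches the 2^n enumeration oracle on random tie-free fixtures", {
  set.seed(17)
  for (n in 3:10) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 6)
      while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(n), 6)
      x <- d; y <- rep(0, n)
      res <- wilcoxon_signed_rank(x, y, mode = "exact")
      expect_equal(res$p_value, min(1, oracle_wilcoxon_exact(d)))
    }
  }
})

test_that("zero handling, ties and the approximation switch behave as documented", {
  expect_error(wilcoxon_signed_rank(rep(1, 5), rep(1, 5)), "zero")
  # tied absolute differences stay exact at small n and match enumeration
  res <- wilcoxon_signed_rank(c(2, 2, 3, 5, 7), c(1, 1, 1, 1, 1))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, min(1, oracle_wilcoxon_exact(c(1, 1, 2, 4, 6))))
  # beyond the exact limit the tie-corrected approximation takes over
  set.seed(1)
  big <- rnorm(40, 0.5)
  resb <- wilcoxon_signed_rank(big, rep(0, 40))
  expect_match(resb$method, "approximation")
  expect_error(wilcoxon_signed_rank(big, rep(0, 40), mode = "exact"),
               "n <= 30")
  # drop policy removes zeros before ranking
  res2 <- wilcoxon_signed_rank(c(0, 1, 2, 3) + c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(res2$n_used, 3L)
})

test_that("Hodges-Lehmann equals Walsh-average enumeration", {
  expect_equal(hodges_lehmann(5.5), 5.5)
  expect_equal(hodges_lehmann(c(1, 2, 3)), 2)     # median of {1,1.5,2,1.5,2.5,3}
  # symmetric sample: equals the sample median
  d <- c(-3, -1, 0, 1, 3)
  expect_equal(hodges_lehmann(d), median(d))
  set.seed(23)
  for (n in c(2, 5, 17, 50)) {
    d <- rnorm(n)
    expect_equal(hodges_lehmann(d), oracle_hl(d))
  }
})

test_that("bootstrap CI is seeded, degenerate on constants, and shrinks with n", {
  expect_equal(bootstrap_ci(rep(0.3, 8), B = 200, seed = 1), c(0.3, 0.3))
  d <- rnorm(11, 0.2, 0.1)
  ci1 <- bootstrap_ci(d, B = 500, seed = 42)
  ci2 <- bootstrap_ci(d, B = 500, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= hodges_lehmann(d) && hodges_lehmann(d) <= ci1[2])
  # interval width shrinks stochastically with n (widths averaged over draws)
  set.seed(31)
  width_at <- function(n) {
    mean(replicate(30, {
      d <- rnorm(n, 0.2, 0.1)
      diff(bootstrap_ci(d, B = 300, seed = sample.int(1e6, 1)))
    }))
  }
  expect_lt(width_at(40), width_at(8))
})

test_that("effect size r is |Z|/sqrt(n), clipped and sign-blind", {
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(2.8, 11), 2.8 / sqrt(11))
  expect_equal(effect_size_r(-2.8, 11), effect_size_r(2.8, 11))
  expect_equal(effect_size_r(50, 4), 1)
  x <- rnorm(12); y <- rnorm(12)
  zx <- wilcoxon_signed_rank(x, y)$z
  zy <- wilcoxon_signed_rank(y, x)$z
  expect_equal(effect_size_r(zx, 12), effect_size_r(zy, 12))
})

test_that("location shift moves the HL estimate exactly and preserves p", {
  set.seed(3)
  d <- rnorm(11, 1, 0.2)          # all positive: adding c > 0 flips no signs
  c0 <- 0.7
  expect_equal(hodges_lehmann(d + c0), hodges_lehmann(d) + c0)
  p1 <- wilcoxon_signed_rank(d, rep(0, 11))$p_value
  p2 <- wilcoxon_signed_rank(d + c0, rep(0, 11))$p_value
  expect_equal(p1, p2)
})

test_that("run_paired_analysis produces one result per index and flags degenerates", {
  set.seed(41)
  subj <- sprintf("s%02d", 1:11)
  tab <- do.call(rbind, lapply(c("TWI", "THI", "StO2", "NIR"), function(ix) {
    h <- runif(11, 0.3, 0.5)
    shift <- if (ix %in% c("TWI", "THI")) 0.1 else 0
    data.frame(subject_id = subj, index = ix,
               cin_mean = h + shift + rnorm(11, 0, 0.02), healthy_mean = h)
  }))
  res <- run_paired_analysis(tab, B = 300, seed = 5)
  expect_length(res, 4L)
  expect_named(res, c("TWI", "THI", "StO2", "NIR"))
  expect_lt(res$TWI$p_value, 0.01)
  expect_gt(res$TWI$hl_estimate, 0)
  expect_true(res$TWI$ci95[1] <= res$TWI$hl_estimate &&
              res$TWI$hl_estimate <= res$TWI$ci95[2])
  expect_true(res$TWI$effect_size_r >= 0 && res$TWI$effect_size_r <= 1)

  # identical columns -> flagged, not tested
  tab0 <- data.frame(subject_id = subj, index = "TWI",
                     cin_mean = 1:11 / 10, healthy_mean = 1:11 / 10)
  res0 <- run_paired_analysis(tab0, B = 300, seed = 5)
  expect_match(res0$TWI$error, "zero")
})
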