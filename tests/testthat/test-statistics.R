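# Smooth per-subject gait-like curves for SPM simulations: a fixed mean
# shape plus random low-order harmonic perturbations per subject.
random_curves <- function(n, amp = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- (0:100) / 100
  base <- 10 * cos(2 * pi * s + 0.5) + 4 * cos(4 * pi * s + 1.3)
  t(vapply(seq_len(n), function(i) {
    pert <- 0
    for (k in 1:3)
      pert <- pert + rnorm(1, sd = amp) * cos(2 * pi * k * s + runif(1, 0, 2 * pi))
    base + pert
  }, numeric(101)))
}

test_that("identical groups produce a flat t-curve and no clusters", {
  A <- random_curves(4, seed = 1)
  res <- spm_ttest2(A, A, alpha = 0.05, n_permutations = 1000, seed = 2)
  expect_equal(res$t_curve, rep(0, 101))
  expect_equal(nrow(res$clusters), 0)
})

test_that("a strong localized offset yields one significant cluster there", {
  set.seed(12)
  A <- random_curves(8)
  B <- random_curves(4)
  sigma <- sd(as.vector(A - colMeans(A)[col(A)]))
  B[, 41:61] <- B[, 41:61] + 5 * sigma
  res <- spm_ttest2(A, B, alpha = 0.05, n_permutations = 1000, seed = 3)
  expect_gte(nrow(res$clusters), 1)
  main <- res$clusters[which.max(res$clusters$max_t), ]
  expect_lt(main$start, 60)
  expect_gt(main$end, 40)
  expect_lt(main$p, 0.05)
})

test_that("two-sample SPM is symmetric under group exchange", {
  A <- random_curves(5, seed = 4)
  B <- random_curves(4, seed = 5)
  r1 <- spm_ttest2(A, B, n_permutations = 2000, seed = 6)
  r2 <- spm_ttest2(B, A, n_permutations = 2000, seed = 6)
  expect_equal(r1$t_curve, -r2$t_curve, tolerance = 1e-12)
  expect_equal(r1$threshold, r2$threshold, tolerance = 1e-12)
  expect_equal(r1$clusters$p, r2$clusters$p, tolerance = 1e-12)
})

test_that("full enumeration is deterministic and seed-independent", {
  A <- random_curves(4, seed = 7)
  B <- random_curves(4, seed = 8)
  r1 <- spm_ttest2(A, B, n_permutations = 10000, seed = 1)
  r2 <- spm_ttest2(A, B, n_permutations = 10000, seed = 999)
  expect_true(r1$exact)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(r1$clusters, r2$clusters)
  expect_equal(r1$n_permutations, choose(8, 4))
})

test_that("SPM input contracts are enforced", {
  A <- random_curves(4, seed = 9)
  expect_error(spm_ttest2(A[1, , drop = FALSE], A),
               class = "ratgait_error_sample_size")
  flat <- matrix(1, 4, 101)
  expect_error(spm_ttest2(flat, flat),
               class = "ratgait_error_degenerate_variance")
})

test_that("paired SPM flags a global shift and ignores none", {
  before <- random_curves(6, seed = 10)
  same <- spm_paired(before, before + rnorm(length(before), sd = 1e-6),
                     n_permutations = 64, seed = 1)
  expect_equal(nrow(same$clusters), 0)

  noise_sd <- sd(as.vector(before - colMeans(before)[col(before)]))
  # a 10-sigma global shift, with subject-level variation so the paired
  # differences have nonzero variance
  set.seed(11)
  after <- before + rnorm(nrow(before), 10 * noise_sd, noise_sd)
  res <- spm_paired(before, after, n_permutations = 64, seed = 1)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, 0)
  expect_equal(res$clusters$end, 100)

  expect_error(spm_paired(before[1, , drop = FALSE],
                          before[1, , drop = FALSE]),
               class = "ratgait_error_sample_size")
})

test_that("paired t-test matches the hand-computed closed form", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 2.4, 2.8, 4.5)
  # closed form: d = y - x, t = mean(d) / (sd(d)/sqrt(n))
  d <- y - x
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  res <- paired_ttest(x, y)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-10)

  expect_error(paired_ttest(x, x), class = "ratgait_error_degenerate_variance")
  expect_error(paired_ttest(x, x + 1), class = "ratgait_error_degenerate_variance")
  expect_error(paired_ttest(1, 2), class = "ratgait_error_sample_size")
})

test_that("one-way ANOVA with Fisher's LSD matches closed forms", {
  # identical groups: no between-group variance
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- anova_fisher_lsd(g0)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_true(all(r0$pairwise$p == 1))

  # hand-computed closed form: groups (1,2,3), (2,3,4), (6,7,8)
  # SSB = 3*((2-4)^2 + (3-4)^2 + (7-4)^2) = 42, MSB = 21
  # SSW = 2 + 2 + 2 = 6, MSW = 1 -> F = 21 with df (2, 6)
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  r <- anova_fisher_lsd(g)
  expect_equal(r$F, 21, tolerance = 1e-10)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 6)
  expect_equal(r$p, 1 - pf(21, 2, 6), tolerance = 1e-12)
  ab <- r$pairwise[r$pairwise$group_i == "a" & r$pairwise$group_j == "b", ]
  expect_equal(ab$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(ab$p, 2 * pt(-abs(ab$t), 6), tolerance = 1e-12)

  expect_error(anova_fisher_lsd(list(1:3)), class = "ratgait_error_sample_size")
  expect_error(anova_fisher_lsd(list(a = 1, b = 1:3)),
               class = "ratgait_error_sample_size")
  expect_error(anova_fisher_lsd(list(a = c(1, 1), b = c(1, 1))),
               class = "ratgait_error_degenerate_variance")
})

test_that("for two groups F equals the squared pooled t", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(7, mean = 0.8)
    r <- anova_fisher_lsd(list(a = a, b = b))
    t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(r$F, unname(t2), tolerance = 1e-10)
  }
})

test_that("the F statistic is invariant to adding a constant", {
  set.seed(14)
  g <- list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(5, 2))
  r1 <- anova_fisher_lsd(g)
  r2 <- anova_fisher_lsd(lapply(g, `+`, 100))
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})

test_that("permutation p-values are super-uniform under the null", {
  # moderate-scale check; the acceptance suite runs the full calibration
  set.seed(15)
  rejections <- 0
  n_rep <- 200
  for (i in 1:n_rep) {
    A <- random_curves(4)
    B <- random_curves(4)
    res <- spm_ttest2(A, B, alpha = 0.05, n_permutations = 1000, seed = i)
    if (nrow(res$clusters) > 0) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})
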