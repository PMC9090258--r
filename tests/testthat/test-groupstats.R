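test_that("exact rank-sum: identical groups, small worked case, errors", {
  expect_equal(wilcoxon_exact(c(3, 3, 3), c(3, 3))$p.value, 1)
  # A = {1,2}, B = {3,4}: 6 assignments, the observed split is one of the
  # two most extreme -> two-sided p = 2/6
  expect_equal(wilcoxon_exact(c(1, 2), c(3, 4))$p.value, 2 / 6)
  expect_error(wilcoxon_exact(numeric(0), 1), "non-empty")
  expect_error(wilcoxon_exact(c(1, NA), c(2, 3)), "finite")
})

test_that("exact rank-sum matches bitmask enumeration, with and without
           ties", {
  set.seed(10)
  for (i in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(1:6, na, replace = TRUE)   # heavy ties
    y <- sample(1:6, nb, replace = TRUE)
    expect_equal(wilcoxon_exact(x, y)$p.value, oracle_wilcoxon_enum(x, y),
                 info = sprintf("instance %d", i))
  }
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6)          # continuous, tie-free
    expect_equal(wilcoxon_exact(x, y)$p.value, oracle_wilcoxon_enum(x, y))
  }
})

test_that("shift-algorithm branch (n > 20) equals the exact distribution", {
  set.seed(11)
  # tie-free case: stats::wilcox.test computes the exact p independently
  x <- rnorm(11); y <- rnorm(12)
  expect_equal(wilcoxon_exact(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # tied case at n = 21 (DP branch): reference value frozen from a direct
  # enumeration of all choose(21, 10) group assignments of the mid-ranks
  x2 <- c(1, 1, 2, 3, 5, 5, 7, 8, 9, 10)
  y2 <- c(1, 2, 2, 4, 5, 6, 6, 8, 11, 12, 13)
  p_dp <- wilcoxon_exact(x2, y2)$p.value
  expect_equal(p_dp, 0.5209403599, tolerance = 1e-9)
})

test_that("rank-sum p is invariant under monotone transforms of the pooled
           data", {
  set.seed(12)
  x <- rexp(6); y <- rexp(7) * 1.5
  p0 <- wilcoxon_exact(x, y)$p.value
  expect_equal(wilcoxon_exact(log(x), log(y))$p.value, p0)
  expect_equal(wilcoxon_exact(x^3, y^3)$p.value, p0)
  expect_equal(wilcoxon_exact(rank(c(x, y))[1:6],
                              rank(c(x, y))[7:13])$p.value, p0)
})

test_that("repeated-measures ANOVA: all-equal degeneracy and SS oracle", {
  flat <- matrix(5, 4, 3)
  r <- rm_anova_log(flat)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)

  m <- matrix(c(2, 5, 9,
                1, 6, 12,
                3, 4, 10,
                2, 7, 15), 4, 3, byrow = TRUE)
  r2 <- rm_anova_log(m)
  expect_equal(unname(r2$statistic), oracle_rm_anova_F(log10(m + 1)),
               tolerance = 1e-10)
  expect_equal(unname(r2$parameter), c(2, 6))
})

test_that("ANOVA transform: scaling that preserves log10(x+1) spacing
           preserves F", {
  m <- matrix(c(2, 5, 9, 1, 6, 12, 3, 4, 10), 3, 3, byrow = TRUE)
  # build m2 so that log10(m2+1) = log10(m+1) + c (adds a constant on the
  # transformed scale, leaving the F statistic unchanged)
  m2 <- 10^(log10(m + 1) + 0.3) - 1
  expect_equal(unname(rm_anova_log(m2)$statistic),
               unname(rm_anova_log(m)$statistic), tolerance = 1e-8)
})

test_that("ANOVA drops incomplete specimens (complete-case) and validates", {
  m <- matrix(c(2, 5, 9, 1, 6, 12, 3, NA, 10, 2, 7, 15), 4, 3,
              byrow = TRUE)
  r <- rm_anova_log(m)
  expect_equal(r$n_complete, 3)
  expect_equal(unname(r$statistic),
               oracle_rm_anova_F(log10(m[-3, ] + 1)), tolerance = 1e-10)
  expect_error(rm_anova_log(m[1:2, 1, drop = FALSE]), "2 regions")
  expect_error(rm_anova_log(matrix(c(1, 2, 3, NA, NA, 4), 3, 2)),
               "complete")
})

test_that("BH adjustment: worked cases and the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:30) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("BH output dominates input and is permutation-equivariant", {
  set.seed(14)
  p <- runif(12)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(12)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})
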