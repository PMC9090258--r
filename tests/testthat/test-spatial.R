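test_that("observation window: square, redundant interior point, degenerate", {
  sq <- observation_window(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area, 1)
  tri <- observation_window(cbind(c(0, 4, 0, 1), c(0, 0, 4, 1)))
  expect_equal(tri$area, 8)
  expect_equal(nrow(tri$vertices), 3)
  expect_error(observation_window(cbind(c(0, 1), c(0, 1))), "3 distinct")
  expect_error(observation_window(cbind(c(0, 1, 2), c(0, 1, 2))),
               "collinear")
})

test_that("intensity estimate: count over area, empty set, Monte-Carlo", {
  win <- observation_window(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  pts <- cbind(runif(100) * 100, runif(100) * 100)
  expect_equal(estimate_intensity(pts, win), 100 / 1e4)
  expect_equal(estimate_intensity(cbind(numeric(0), numeric(0)), win), 0)

  # homogeneous simulation at lambda = 0.002 recovered within 3 SE
  regs <- generate_regions(300, 100)
  dens <- list(edge = c(CD3 = 0.002), tumor = c(CD3 = 0.002),
               necrosis = c(CD3 = 0.002))
  est <- vapply(1:200, function(s) {
    cells <- simulate_cells(regs, simulation_config(300, 100,
                                                    densities = dens,
                                                    seed = s))
    nrow(cells) / 3e4   # true window area
  }, numeric(1))
  se <- sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - 0.002), 3 * se)
})

test_that("closed-form CSR G-function", {
  expect_equal(theoretical_g(0, 10), 0)
  expect_equal(theoretical_g(0.01, 0), 0)
  expect_equal(theoretical_g(0.002, 15), 1 - exp(-0.002 * pi * 225))
  expect_error(theoretical_g(-1, 5), ">= 0")
})

test_that("empirical G: step case, thirds case, empty conventions", {
  g <- empirical_cross_g(cbind(0, 0), cbind(10, 0))
  expect_equal(g$G[g$r < 10], rep(0, sum(g$r < 10)))
  expect_equal(g$G[g$r >= 10], rep(1, sum(g$r >= 10)))

  # nearest-target distances {5, 20, 40} -> G(15) = 1/3
  ref <- cbind(c(0, 100, 200), c(0, 0, 0))
  tgt <- cbind(c(5, 120, 240), c(0, 0, 0))
  g2 <- empirical_cross_g(ref, tgt)
  expect_equal(g2$G[g2$r == 15], 1 / 3)
  expect_equal(g2$G, oracle_cross_g(ref, tgt, g2$r))

  # no target cells: G identically 0 and a negative score
  g3 <- empirical_cross_g(ref, cbind(numeric(0), numeric(0)))
  expect_true(all(g3$G == 0))
  expect_false(g_auc(g3)$interaction_score)
  expect_error(empirical_cross_g(ref, tgt, r_grid = c(0, 2, 1)),
               "increasing")
})

test_that("G AUC: flat curves, step-curve trapezoid oracle, grid errors", {
  ref <- cbind(c(0, 100), c(0, 0))
  g0 <- empirical_cross_g(ref, cbind(numeric(0), numeric(0)))
  expect_equal(g_auc(g0)$auc, 0)

  g1 <- empirical_cross_g(cbind(0, 0), cbind(0, 0))  # G = 1 everywhere
  expect_equal(g_auc(g1, 15)$auc, 15)

  gs <- empirical_cross_g(cbind(0, 0), cbind(10, 0))    # step at r = 10
  a <- g_auc(gs, 15)
  expect_equal(a$auc, oracle_trapezoid(gs$r, gs$G, 15))
  expect_equal(a$auc_pct, 100 * a$auc / 15)
  expect_error(g_auc(gs, 60), "outside")
})

test_that("empirical G, AUC and pair counts match brute force on random
           instances", {
  for (seed in 1:20) {
    set.seed(seed)
    nr <- sample(1:60, 1); nt <- sample(0:60, 1)
    ref <- cbind(runif(nr, 0, 200), runif(nr, 0, 200))
    tgt <- cbind(runif(nt, 0, 200), runif(nt, 0, 200))
    g <- empirical_cross_g(ref, tgt)
    expect_identical(g$G, oracle_cross_g(ref, tgt, g$r))
    expect_equal(g_auc(g, 15)$auc, oracle_trapezoid(g$r, g$G, 15))
    pc <- cross_pair_counts(ref, tgt, radius = 15)
    expect_identical(pc$counts, as.integer(oracle_pair_counts(ref, tgt, 15)))
  }
})

test_that("pair counts: inclusive 15 um boundary and self-exclusion", {
  ref <- data.frame(cell_id = "r1", x_um = 0, y_um = 0)
  tgt <- data.frame(cell_id = paste0("t", 1:4),
                    x_um = c(5, 14.9, 15, 16), y_um = 0)
  pc <- cross_pair_counts(ref, tgt, radius = 15)
  expect_equal(pc$counts, 3L)   # 5, 14.9 and exactly 15.0 count; 16 does not

  # same phenotype on both sides: a cell never counts itself
  pts <- data.frame(cell_id = paste0("c", 1:3),
                    x_um = c(0, 5, 40), y_um = 0)
  self <- cross_pair_counts(pts, pts, radius = 15)
  expect_equal(self$counts, c(1L, 1L, 0L))
  expect_equal(self$counts,
               as.integer(oracle_pair_counts(as.matrix(pts[, 2:3]),
                                             as.matrix(pts[, 2:3]),
                                             15, self = TRUE)))
  expect_error(cross_pair_counts(ref, tgt, radius = 0), "radius")
})

test_that("statistics are translation invariant", {
  set.seed(7)
  ref <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  tgt <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  shift <- c(1234.5, -987.6)
  g1 <- empirical_cross_g(ref, tgt)
  g2 <- empirical_cross_g(sweep(ref, 2, -shift), sweep(tgt, 2, -shift))
  expect_equal(g2$G, g1$G)
  expect_equal(g2$lambda_y, g1$lambda_y)
  p1 <- cross_pair_counts(ref, tgt)
  p2 <- cross_pair_counts(sweep(ref, 2, -shift), sweep(tgt, 2, -shift))
  expect_equal(p2$counts, p1$counts)
})

test_that("empirical G is a CDF on the grid and the border-corrected
           variant stays within [0, 1]", {
  for (seed in 1:10) {
    set.seed(seed)
    ref <- cbind(runif(30, 0, 150), runif(30, 0, 150))
    tgt <- cbind(runif(25, 0, 150), runif(25, 0, 150))
    g <- empirical_cross_g(ref, tgt)
    expect_true(all(diff(g$G) >= 0))
    expect_true(all(g$G >= 0 & g$G <= 1))
    win <- observation_window(rbind(ref, tgt))
    gb <- empirical_cross_g(ref, tgt, correction = "border", window = win)
    ok <- !is.na(gb$G)
    expect_true(all(gb$G[ok] >= 0 & gb$G[ok] <= 1))
  }
})

test_that("cluster frequency thresholds: 2 partners make a cluster, 1 does
           not; mixed criterion needs one of each", {
  ref <- data.frame(cell_id = paste0("r", 1:10),
                    x_um = seq(0, 900, by = 100), y_um = 0)
  # refs 1..3 get two partners, ref 4 gets one
  tgt <- data.frame(cell_id = paste0("t", 1:7),
                    x_um = c(1, 2, 101, 102, 201, 202, 301), y_um = 0)
  pc <- cross_pair_counts(ref, tgt, radius = 15)
  cf <- cluster_frequency(pc)
  expect_equal(cf$frequency, 30)   # 3 of 10 reference cells
  expect_equal(cf$n_members, 3)

  tgt2 <- data.frame(cell_id = "u1", x_um = 1, y_um = 1)
  pc2 <- cross_pair_counts(ref, tgt2, radius = 15)
  cf2 <- cluster_frequency(pc, pc2)   # >= 1 of each type
  expect_equal(cf2$n_members, 1)      # only ref 1 has both types

  empty <- cross_pair_counts(ref[0, ], tgt, radius = 15)
  cfe <- cluster_frequency(empty)
  expect_true(cfe$empty)
  expect_true(is.na(cfe$frequency))
})

test_that("mean empirical G under CSR tracks the closed form away from
           edges", {
  # interior reference grid; targets Poisson at lambda in a 500x500 window
  lambda <- 0.002
  refs <- as.matrix(expand.grid(x = seq(100, 400, length.out = 10),
                                y = seq(100, 400, length.out = 10)))
  G15 <- vapply(1:100, function(s) {
    set.seed(s)
    n <- rpois(1, lambda * 500 * 500)
    tgt <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    g <- empirical_cross_g(refs, tgt)
    g$G[g$r == 15]
  }, numeric(1))
  se <- sd(G15) / sqrt(100)
  expect_lt(abs(mean(G15) - theoretical_g(lambda, 15)), 3 * se)
})

test_that("planted attraction only increases the mean dyad AUC", {
  regs <- generate_regions(450, 300)
  mean_auc <- function(k) {
    aucs <- vapply(1:50, function(s) {
      cfg <- small_config(seed = s)
      cells <- simulate_cells(regs, cfg)
      if (k > 0)
        cells <- plant_interactions(
          cells, regs, attraction_entry("CD3", "CD163", "tumor", k = k,
                                        k_type = "fixed", radius = 10),
          seed = s + 5000)
      tum <- cells[cells$region_class == "tumor", ]
      g <- empirical_cross_g(tum[tum$phenotype_truth == "CD3", ],
                             tum[tum$phenotype_truth == "CD163", ])
      g_auc(g)$auc
    }, numeric(1))
    mean(aucs)
  }
  m <- c(mean_auc(0), mean_auc(1), mean_auc(3))
  expect_true(all(diff(m) > 0))
})
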