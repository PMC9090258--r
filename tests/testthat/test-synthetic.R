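test_that("identical config and seed reproduce the table bitwise", {
  cfg <- small_config(seed = 11)
  a <- simulate_specimen(cfg)
  b <- simulate_specimen(cfg)
  expect_identical(a$cells, b$cells)
  c2 <- simulate_specimen(small_config(seed = 12))
  expect_false(identical(a$cells, c2$cells))
})

test_that("zero intensity everywhere yields an empty table", {
  dens <- lapply(default_densities(), function(v) v * 0)
  cfg <- small_config(seed = 1, densities = dens)
  cells <- simulate_cells(generate_regions(450, 300), cfg)
  expect_equal(nrow(cells), 0)
})

test_that("per-region counts are Poisson-calibrated (mean and dispersion)", {
  regs <- generate_regions(300, 100)   # tumor band area 10,000 um^2
  dens <- list(edge = c(CD3 = 0), tumor = c(CD3 = 0.01),
               necrosis = c(CD3 = 0))
  counts <- vapply(1:500, function(i) {
    cfg <- simulation_config(window_width = 300, window_height = 100,
                             densities = dens, seed = i)
    nrow(simulate_cells(regs, cfg))
  }, numeric(1))
  mu <- 0.01 * 10000
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("planting conserves offspring counts and the radius bound", {
  regs <- generate_regions(450, 300)
  cfg <- small_config(seed = 5)
  cells <- simulate_cells(regs, cfg)
  entry <- attraction_entry("CD3", "CD163", "tumor", k = 2,
                            k_type = "fixed", radius = 10)
  parents <- sum(cells$phenotype_truth == "CD3" &
                   cells$region_class == "tumor")
  expect_gt(parents, 0)
  out <- plant_interactions(cells, regs, entry, seed = 7)
  expect_equal(nrow(out), nrow(cells) + 2 * parents)
  off <- out[!is.na(out$interaction_id), ]
  par <- out[match(off$interaction_id, out$cell_id), ]
  d <- sqrt((off$x_um - par$x_um)^2 + (off$y_um - par$y_um)^2)
  expect_true(all(d <= 10 + 1e-9))
  expect_true(all(off$phenotype_truth == "CD163"))
  expect_true(all(off$region_class == "tumor"))
})

test_that("planting with no parents warns and returns the input unchanged", {
  regs <- generate_regions(450, 300)
  dens <- list(edge = c(CD68 = 1e-3), tumor = c(CD68 = 1e-3),
               necrosis = c(CD68 = 1e-4))
  cells <- simulate_cells(regs, simulation_config(450, 300,
                                                  densities = dens,
                                                  seed = 2))
  entry <- attraction_entry("CD3", "CD163", "tumor", k = 2)
  expect_warning(out <- plant_interactions(cells, regs, entry, seed = 1),
                 "unchanged")
  expect_identical(out, cells)
})

test_that("gradient counts follow the exponential intensity profile", {
  # lambda_far = 0, decay 20 um: expected strip counts proportional to
  # exp(-d/20); compare binned means over 200 seeds with the closed form
  reg <- region_annotation("e", "edge",
                           cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  entry <- gradient_entry("CD163", "edge", lambda_near = 0.02,
                          lambda_far = 0, decay_length = 20, from = "xmax")
  breaks <- seq(0, 100, by = 20)
  tot <- numeric(length(breaks) - 1)
  for (s in 1:200) {
    cells <- simulate_gradient(reg, entry, seed = s)
    d <- 100 - cells$x_um
    tot <- tot + hist(d, breaks = breaks, plot = FALSE)$counts
  }
  expected <- 0.02 * 100 * 20 * (exp(-breaks[-length(breaks)] / 20) -
                                   exp(-breaks[-1] / 20))
  obs <- tot / 200
  # each bin within 3 SE of its closed-form Poisson mean
  expect_true(all(abs(obs - expected) <= 3 * sqrt(expected / 200) + 1e-9))

  expect_equal(nrow(simulate_gradient(
    reg, gradient_entry("CD163", "edge", 0, 0, 20), seed = 1)), 0)
  expect_error(gradient_entry("CD163", "edge", 0.001, 0.002, 20),
               "lambda_near")
})

test_that("intensity simulation errors on unknown phenotype labels", {
  cells <- data.frame(cell_id = "c1", x_um = 1, y_um = 1,
                      phenotype_truth = "CD99", pstat3_truth = FALSE)
  expect_error(simulate_intensities(cells, default_gates(), 0, seed = 1),
               "unknown phenotype")
})

test_that("a single-marker cell stays below all other gates at zero noise", {
  cells <- data.frame(cell_id = "c1", x_um = 1, y_um = 1,
                      phenotype_truth = "CD3", pstat3_truth = FALSE)
  out <- simulate_intensities(cells, default_gates(), 0, seed = 1)
  g <- default_gates()
  expect_true(out$CD3_intensity >= g$CD3$intensity_threshold)
  for (m in c("CD68", "CD11c", "CD163", "pSTAT3")) {
    expect_lt(out[[paste0(m, "_intensity")]],
              g[[m]]$intensity_threshold)
    expect_lt(out[[paste0(m, "_coverage")]],
              g[[m]]$coverage_threshold)
  }
})

test_that("re-gating recovers phenotype truth: exactly at zero noise,
           and a measured recovery rate under moderate noise", {
  regs <- generate_regions(450, 300)
  cfg <- small_config(seed = 21)
  cells <- simulate_cells(regs, cfg)
  noiseless <- simulate_intensities(cells, cfg$gates, 0, seed = 3)
  gated <- classify_cells(noiseless, cfg$gates)
  expect_equal(gated$phenotype, gated$phenotype_truth)
  expect_equal(gated$pstat3, gated$pstat3_truth)

  noisy <- simulate_intensities(cells, cfg$gates, 0.5, seed = 3)
  gated2 <- classify_cells(noisy, cfg$gates)
  recovery <- mean(gated2$phenotype == gated2$phenotype_truth)
  expect_gt(recovery, 0.8)   # imperfect but high under moderate noise
  expect_lt(recovery, 1)     # noise must actually flip some cells
})
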