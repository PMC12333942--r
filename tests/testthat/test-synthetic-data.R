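test_that("cell map generation is reproducible and respects zero density", {
  cfg <- small_cell_config(seed = 4)
  a <- generate_cell_map(cfg)
  b <- generate_cell_map(cfg)
  expect_identical(a, b)
  # zero densities, no TLS: empty table
  cfg0 <- tissue_sim_config(
    regions = data.frame(region_id = "r", tissue_class = "normal",
                         xmin = 0, ymin = 0, xmax = 1000, ymax = 1000),
    densities = data.frame(tissue_class = "normal", phenotype = "T_cell",
                           per_mm2 = 0),
    tls_specs = NULL, seed = 1)
  expect_equal(nrow(generate_cell_map(cfg0)$cells), 0)
})

test_that("background counts follow Poisson(density x area) moments", {
  cfg <- tissue_sim_config(
    regions = data.frame(region_id = "r", tissue_class = "normal",
                         xmin = 0, ymin = 0, xmax = 1000, ymax = 1000),
    densities = data.frame(tissue_class = "normal", phenotype = "T_cell",
                           per_mm2 = 100),
    tls_specs = NULL, seed = 1)
  counts <- vapply(1:100, function(s) {
    cfg$seed <- s
    nrow(generate_cell_map(cfg)$cells)
  }, 0)
  # mean within 4 standard errors of lambda = 100
  expect_lt(abs(mean(counts) - 100), 4 * sqrt(100 / 100))
  expect_true(all(counts >= 0))
})

test_that("mature TLS discs have a germinal-center core with a T-cell annulus", {
  cfg <- tissue_sim_config(
    regions = data.frame(region_id = "r", tissue_class = "PDAC",
                         xmin = 0, ymin = 0, xmax = 1000, ymax = 1000),
    densities = data.frame(tissue_class = "PDAC", phenotype = "T_cell",
                           per_mm2 = 0),
    tls_specs = data.frame(center_x = 500, center_y = 500, radius_um = 150,
                           maturity = "mature", n_cells = 200),
    seed = 6)
  sim <- generate_cell_map(cfg)
  r <- sqrt((sim$cells$x_um - 500)^2 + (sim$cells$y_um - 500)^2)
  gc <- sim$truth$cells$phenotype == "B_germinal_center"
  expect_gt(sum(gc), 0)
  expect_true(all(r[gc] <= 75 + 1e-9))         # inner disc
  expect_false(any(r > 75 & gc))               # none in the annulus
  expect_true(all(r <= 150 + 1e-9))
  # misplaced disc errors
  cfg$tls_specs$center_x <- 5000
  expect_error(generate_cell_map(cfg), "outside all regions")
})

test_that("overlapping region rectangles are rejected", {
  expect_error(tissue_sim_config(
    regions = data.frame(region_id = c("a", "b"),
                         tissue_class = c("normal", "PanIN"),
                         xmin = c(0, 500), ymin = 0,
                         xmax = c(1000, 1500), ymax = 1000)),
    "overlap")
})

test_that("noiseless rank-1 spot data reproduces the planted log2 means", {
  u <- c(3, 2, 2, 4); v <- rep(c(1, 0.9), 8)
  A <- matrix(u, 4, 1, dimnames = list(paste0("g", 1:4), NULL))
  P <- matrix(v, 1, 16)
  cfg <- visium_sim_config(n_rows = 4, n_cols = 8, A_true = A, P_true = P,
                           delta = 0, noise = "none", seed = 1)
  sim <- generate_spot_data(cfg)
  M <- u %*% t(v)
  D <- log_transform(sim$spots$counts)
  expect_lt(max(abs(D - M)), 0.25)  # only rounding error of round(2^M - 1)
})

test_that("delta = 0 leaves TLS and other spots with the same generative law", {
  A <- matrix(2, 50, 1, dimnames = list(paste0("g", 1:50), NULL))
  P <- matrix(1, 1, 50)
  cfg <- visium_sim_config(n_rows = 10, n_cols = 10, A_true = A, P_true = P,
                           delta = 0, noise = "none", tls_spots = 1:10,
                           libsize_sdlog = 0, seed = 2)
  sim <- generate_spot_data(cfg)
  counts <- as.matrix(sim$spots$counts)
  expect_equal(counts[, 1:10], counts[, 11:20],
               ignore_attr = TRUE)  # identical deterministic law
})

test_that("poisson spot counts match the generator's first moment", {
  # mean 2^M - 1 = 10 over ~1000 spots
  A <- matrix(log2(11), 20, 1, dimnames = list(paste0("g", 1:20), NULL))
  P <- matrix(1, 1, 1012)
  cfg <- visium_sim_config(n_rows = 44, n_cols = 46, A_true = A, P_true = P,
                           delta = 0, libsize_sdlog = 0, seed = 3)
  sim <- generate_spot_data(cfg)
  m <- mean(as.matrix(sim$spots$counts)[1, ])
  n_spots <- ncol(sim$spots$counts)
  expect_lt(abs(m - 10), 3 * sqrt(10 / n_spots))
})

test_that("spot data is reproducible, integral, and lattice-conforming", {
  cfg <- visium_sim_config(n_rows = 10, n_cols = 12, n_genes = 80, seed = 5)
  a <- generate_spot_data(cfg)
  b <- generate_spot_data(cfg)
  expect_identical(as.matrix(a$spots$counts), as.matrix(b$spots$counts))
  counts <- as.matrix(a$spots$counts)
  expect_true(all(counts >= 0 & counts == round(counts)))
  expect_true(all((a$spots$positions$array_row +
                     a$spots$positions$array_col) %% 2 == 0))
})

test_that("cell map and spot data round-trip through their file formats", {
  dir <- tempfile()
  sim <- generate_cell_map(small_cell_config(seed = 2))
  write_cell_map(sim, dir)
  cells_back <- utils::read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells_back), nrow(sim$cells))
  expect_equal(cells_back$x_um, sim$cells$x_um)
  ssim <- generate_spot_data(visium_sim_config(n_rows = 8, n_cols = 8,
                                               n_genes = 60, seed = 2))
  sdir <- tempfile()
  write_spot_data(ssim, sdir)
  back <- read_spot_data(sdir)
  expect_equal(as.matrix(back$counts), as.matrix(ssim$spots$counts))
  expect_equal(back$positions$array_row, ssim$spots$positions$array_row)
})
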