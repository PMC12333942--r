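two_region_set <- list(region_rect("A", "PanIN", 0, 0, 2000, 1000),
                       region_rect("B", "PDAC", 3000, 0, 4000, 1000))

test_that("density is count over area and counts are conserved", {
  cells <- data.frame(cell_id = 1:60,
                      x_um = runif(60, 0, 2000), y_um = runif(60, 0, 1000),
                      region_id = "A",
                      phenotype = rep(c("T_cell", "B_cell", "unassigned"),
                                      c(50, 6, 4)))
  rec <- cell_density(cells, two_region_set)
  expect_equal(rec$density[rec$region_id == "A" & rec$phenotype == "T_cell"], 25)
  # empty region reports zero for every phenotype
  expect_true(all(rec$count[rec$region_id == "B"] == 0))
  # conservation incl. unassigned
  expect_equal(sum(rec$count), nrow(cells))
  expect_equal(rec$density * rec$area_mm2, rec$count)
})

test_that("density ratio divides densities and treats empty denominators as missing", {
  cells <- data.frame(cell_id = 1:40,
                      x_um = 0, y_um = 0, region_id = "A",
                      phenotype = rep(c("T_CD8", "Treg"), c(30, 10)))
  rec <- cell_density(cells, two_region_set[1])
  ratio <- density_ratio(rec, "T_CD8", "Treg")
  expect_equal(ratio$ratio, 3.0)
  # area cancels: same counts in a different-size region give the same ratio
  cells2 <- cells; cells2$region_id <- "B"
  ratio2 <- density_ratio(cell_density(cells2, two_region_set[2]),
                          "T_CD8", "Treg")
  expect_equal(ratio2$ratio, 3.0)
  # zero denominator: NA with warning, not Inf
  cells3 <- cells; cells3$phenotype <- "T_CD8"
  cells3$phenotype[1] <- "Treg"; cells3 <- cells3[cells3$phenotype == "T_CD8" | 1:40 == 1, ]
  rec3 <- cell_density(data.frame(cell_id = 1:5, x_um = 0, y_um = 0,
                                  region_id = "A",
                                  phenotype = c("T_CD8", "T_CD8", "T_CD8",
                                                "T_CD8", "Treg")),
                       two_region_set[1])
  rec3$density[rec3$phenotype == "Treg"] <- 0
  rec3$count[rec3$phenotype == "Treg"] <- 0
  expect_warning(r <- density_ratio(rec3, "T_CD8", "Treg"), "absent")
  expect_true(is.na(r$ratio))
  expect_error(density_ratio(rec3, "T_CD8", "NK"), "unknown phenotype")
})

test_that("wilcoxon exact mode reproduces the enumeration oracle", {
  # canonical case: complete separation of 3 vs 3 gives two-sided p = 0.1
  res <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  expect_match(res$method, "exact")
  # exhaustive agreement for all n1, n2 <= 7 on random tie-free data
  set.seed(21)
  for (n1 in 2:7) for (n2 in 2:7) {
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    got <- compare_groups(c(x, y), rep(c("a", "b"), c(n1, n2)))$p_value
    expect_equal(got, oracle_wilcoxon_exact(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("degenerate and tied inputs fall back sensibly", {
  expect_equal(compare_groups(rep(1, 4), c("a", "a", "b", "b"))$p_value, 1)
  # ties force the corrected normal approximation
  res <- compare_groups(c(1, 1, 2, 3, 2, 2, 3, 4),
                        rep(c("a", "b"), each = 4))
  expect_match(res$method, "approx")
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(compare_groups(c(1, 2), c("a", "b")), ">= 2 observations")
})

test_that("wilcoxon and kruskal-wallis are calibrated under the null", {
  set.seed(97)
  n_sim <- 2000
  rej_w <- 0; rej_k <- 0
  for (i in seq_len(n_sim)) {
    v <- rnorm(30)
    g2 <- rep(c("a", "b"), 15)
    g3 <- rep(c("a", "b", "c"), 10)
    rej_w <- rej_w + (compare_groups(v[1:20], g2[1:20] )$p_value <= 0.05)
    rej_k <- rej_k + (compare_groups(v, g3, test = "kruskal")$p_value <= 0.05)
  }
  expect_gte(rej_w / n_sim, 0.03); expect_lte(rej_w / n_sim, 0.07)
  expect_gte(rej_k / n_sim, 0.03); expect_lte(rej_k / n_sim, 0.07)
})

test_that("a planted 3-fold density difference is detected with high power", {
  set.seed(13)
  n_sim <- 200
  hits <- 0
  for (i in seq_len(n_sim)) {
    low <- rlnorm(10, log(20), sqrt(log(1 + 0.3^2)))
    high <- rlnorm(10, log(60), sqrt(log(1 + 0.3^2)))
    p <- compare_groups(c(low, high), rep(c("lo", "hi"), each = 10))$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("marker expression comparison detects planted shifts and stays calibrated", {
  set.seed(5)
  # power: delta = 1 in transformed units, n = 100 per group
  hits <- 0
  for (i in 1:100) {
    cells <- data.frame(cell_id = 1:200, x_um = 0, y_um = 0, region_id = "r",
                        PD1 = c(rnorm(100, 1), rnorm(100, 2)))
    g <- rep(c("PanIN", "PDAC"), each = 100)
    hits <- hits + (compare_marker_expression(cells, "PD1", g)$p_value < 0.001)
  }
  expect_gte(hits / 100, 0.95)
  expect_error(compare_marker_expression(
    data.frame(cell_id = 1, x_um = 0, y_um = 0, region_id = "r", PD1 = 1),
    "CD3", "a"), "unknown marker")
})
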