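# A disc of lymphoid cells in a sparse background, built directly.
disc_cells <- function(n, cx, cy, radius, phenotype = "B_cell",
                       id_offset = 0, seed = 1) {
  set.seed(seed)
  r <- radius * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  data.frame(cell_id = id_offset + seq_len(n),
             x_um = cx + r * cos(a), y_um = cy + r * sin(a),
             region_id = "r", phenotype = phenotype)
}

test_that("a planted dense disc is detected as one aggregate", {
  disc <- disc_cells(300, 500, 500, 150, seed = 2)
  sparse <- data.frame(cell_id = 201:240,
                       x_um = runif(40, 1500, 4000), y_um = runif(40, 0, 2000),
                       region_id = "r", phenotype = "T_cell")
  tls <- detect_aggregates(rbind(disc, sparse))
  expect_equal(length(tls), 1)
  expect_gte(mean(disc$cell_id %in% tls[[1]]$cell_ids), 0.95)
})

test_that("sparse fields yield no aggregates and two discs yield two", {
  set.seed(9)
  sparse <- data.frame(cell_id = 1:100,
                       x_um = runif(100, 0, 5000), y_um = runif(100, 0, 5000),
                       region_id = "r", phenotype = "T_cell")
  expect_equal(length(detect_aggregates(sparse)), 0)
  two <- rbind(disc_cells(250, 500, 500, 120, seed = 3),
               disc_cells(250, 1500, 500, 120, id_offset = 250, seed = 4))
  expect_equal(length(detect_aggregates(two)), 2)
  # non-lymphoid cells are never clustered
  fibro <- disc_cells(250, 500, 500, 120, phenotype = "fibroblast", seed = 5)
  expect_equal(length(detect_aggregates(fibro)), 0)
})

test_that("TLS-lesion association applies the 250 um rule with deterministic ties", {
  regions <- list(region_rect("les1", "PanIN", 0, 0, 1000, 1000),
                  region_rect("les2", "PDAC", 1420, 0, 2420, 1000))
  hull <- function(cx) {
    structure(list(tls_id = 1L, cell_ids = 1:60,
                   hull = cbind(cx + c(-50, 50, 50, -50), c(450, 450, 550, 550)),
                   hull_area_mm2 = 0.01, centroid = c(cx, 500),
                   lesion_class = NA, lesion_distance_um = NA),
              class = "tls_record")
  }
  # 200 um from PanIN edge, farther from PDAC -> PanIN
  t1 <- associate_tls(hull(1250), list(regions[[1]]))
  expect_equal(t1$lesion_class, "PanIN")
  expect_equal(t1$lesion_distance_um, 200)
  # 300 um from the nearest lesion -> excluded
  t2 <- associate_tls(hull(1350), list(regions[[1]]))
  expect_equal(t2$lesion_class, "excluded")
  expect_equal(t2$lesion_distance_um, 300)
  # exactly equidistant (160 um to each): first region in order wins, logged
  expect_message(t3 <- associate_tls(hull(1210), regions), "equidistant")
  expect_equal(t3$lesion_class, "PanIN")
  # normal tissue does not qualify as a lesion
  t4 <- associate_tls(hull(1250),
                      list(region_rect("n", "normal", 0, 0, 1000, 1000)))
  expect_equal(t4$lesion_class, "excluded")
})

test_that("composition fractions cover lymphoid members and sum to one", {
  cells <- rbind(disc_cells(120, 500, 500, 100, "B_cell", seed = 6),
                 disc_cells(80, 500, 500, 100, "T_CD4", 120, seed = 7))
  tls <- detect_aggregates(cells, min_cells = 50)
  expect_equal(length(tls), 1)
  comp <- tls_composition(tls[[1]], cells)
  expect_equal(sum(comp$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(comp$fractions["B_cell"]), 0.6, tolerance = 0.02)
  expect_equal(comp$n_other, 0)
})

test_that("maturity calls require enough interior germinal-center B cells", {
  sim <- generate_cell_map(small_cell_config(seed = 3))
  ct <- phenotype_cells(sim)
  tls <- lapply(detect_aggregates(ct), associate_tls, regions = sim$regions)
  expect_equal(length(tls), 2)
  tab <- tls_table(tls, ct)
  # match detection to planted truth by centroid
  truth <- sim$truth$tls
  for (i in seq_len(nrow(tab))) {
    cen <- colMeans(ct[ct$cell_id %in% tls[[i]]$cell_ids, c("x_um", "y_um")])
    j <- which.min((truth$center_x - cen[1])^2 + (truth$center_y - cen[2])^2)
    expect_equal(tab$maturity[i], truth$maturity[j])
    expect_equal(tab$lesion_class[i], truth$tissue_class[j])
  }
  # metrics are count / hull area to machine precision
  m <- classify_maturity(tls[[1]], ct)
  hull_poly <- region_polygon("h", "TLS", tls[[1]]$hull)
  inside <- signed_boundary_distance(cbind(ct$x_um, ct$y_um), hull_poly) <= 0
  expect_equal(m$metrics$gc_b_density,
               sum(inside & ct$phenotype == "B_germinal_center") /
                 tls[[1]]$hull_area_mm2)
})

test_that("the germinal-center count threshold is a strict minimum", {
  # 9 GC-B cells at the centre of a B-cell aggregate: immature at threshold 10
  cells <- rbind(disc_cells(220, 500, 500, 120, "B_cell", seed = 8),
                 disc_cells(9, 500, 500, 20, "B_germinal_center", 220, seed = 9))
  tls <- detect_aggregates(cells)
  expect_equal(length(tls), 1)
  expect_equal(classify_maturity(tls[[1]], cells, gc_min_cells = 10)$maturity,
               "immature")
  expect_equal(classify_maturity(tls[[1]], cells, gc_min_cells = 9)$maturity,
               "mature")
})
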