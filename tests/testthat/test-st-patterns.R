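toy_spot_matrix <- function(n_genes = 30, n_rows = 6, n_cols = 10, seed = 1,
                            composition = NULL, segment_id = NULL) {
  set.seed(seed)
  lat <- hex_lattice(n_rows, n_cols)
  n <- nrow(lat$spots)
  counts <- matrix(rpois(n_genes * n, 12), n_genes, n,
                   dimnames = list(sprintf("g%02d", 1:n_genes),
                                   sprintf("s%02d", 1:n)))
  pos <- data.frame(barcode = colnames(counts),
                    array_row = lat$spots$array_row,
                    array_col = lat$spots$array_col,
                    x_um = lat$spots$x_um, y_um = lat$spots$y_um)
  spot_matrix(counts, pos, composition = composition, segment_id = segment_id)
}

test_that("spot filtering applies the three QC rules like a per-rule oracle", {
  sm <- toy_spot_matrix(seed = 2)
  n <- ncol(sm$counts)
  comp <- data.frame(ductal = rep(0.2, n), collagen = 0.6, fat = 0.1)
  comp[1, ] <- c(0.75, 0.25, 0)    # labeled ductal
  comp[2, ] <- c(0.1, 0.1, 0.8)    # fat: removed
  comp[3, ] <- c(0.1, 0.1, 0.05)   # non-tissue 0.75: removed
  sm$composition <- comp
  # one low-UMI segment
  seg <- rep("good", n); seg[4:6] <- "bad"
  sm$segment_id <- seg
  sm$counts[, 4:6] <- 0
  sm$counts[1, 4:6] <- c(1, 2, 1)
  expect_message(out <- filter_spots(sm, min_segment_median_umi = 200),
                 "removing")
  # oracle: apply the three rules independently
  top <- apply(as.matrix(comp), 1, max)
  lab <- colnames(comp)[apply(as.matrix(comp), 1, which.max)]
  drop <- (top >= 0.7 & lab == "fat") | (1 - rowSums(comp) >= 0.7) |
    seg == "bad"
  expect_equal(ncol(out$counts), sum(!drop))
  expect_setequal(attr(out, "removed")$barcode, sm$barcodes[drop])
  expect_equal(out$tissue_class[out$barcodes == "s01"], "ductal")
  # mixed spot (no 70% class) survives but is unlabeled
  expect_true(is.na(out$tissue_class[out$barcodes == "s07"]))
})

test_that("TLS spot labeling partitions spots and expands two hex rings", {
  sm <- toy_spot_matrix(n_rows = 12, n_cols = 20, seed = 3)
  # hull around one interior spot
  i <- which(sm$positions$array_row == 6 & sm$positions$array_col == 10)
  hull <- list(list(tls_id = 1,
                    hull = cbind(sm$positions$x_um[i] + c(-20, 20, 20, -20),
                                 sm$positions$y_um[i] + c(-20, -20, 20, 20)),
                    centroid = c(sm$positions$x_um[i], sm$positions$y_um[i])))
  out <- label_tls_spots(sm, hull, depth = 2)
  expect_equal(sum(out$label == "TLS:1"), 1)
  expect_equal(sum(out$label == "TLS_neighbor"), 18)
  expect_true(all(out$label %in% c("TLS:1", "TLS_neighbor", "other")))
  expect_error(label_tls_spots(sm, hull, depth = 0), "depth")
})

test_that("log transform hits exact powers and rejects negatives", {
  m <- matrix(c(0, 1, 7, 15), 2, 2)
  expect_equal(log_transform(m), matrix(c(0, 1, 3, 4), 2, 2))
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("NMF recovers an exact rank-1 factorization and keeps the objective monotone", {
  set.seed(4)
  u <- runif(40, 0.5, 3); v <- runif(30, 0.2, 1)
  D <- u %*% t(v)
  fit <- fit_nmf(D, K = 1, alpha = 0, seed = 2, n_restarts = 2)
  expect_lt(norm(D - fit$A %*% fit$P, "F") / norm(D, "F"), 1e-3)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # random data keeps monotonicity too, with the L1 penalty active
  D2 <- matrix(runif(600), 30, 20)
  fit2 <- fit_nmf(D2, K = 3, alpha = 0.01, seed = 5, max_iter = 300)
  expect_true(all(diff(fit2$objective_trace) <= 1e-8))
  # P rows rescaled to max 1
  expect_equal(unname(apply(fit2$P, 1, max)), rep(1, 3))
  expect_error(fit_nmf(D2, K = 50), "K must be")
  expect_error(fit_nmf(matrix(0, 5, 5), K = 2), "all zero")
})

test_that("NMF recovers planted patterns from noisy counts", {
  sim <- generate_spot_data(visium_sim_config(seed = 31))
  fit <- fit_nmf(log_transform(sim$spots$counts), K = 3, seed = 7)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- max(vapply(perms, function(p) {
    mean(vapply(1:3, function(k) cosine(fit$P[p[k], ], sim$truth$P_true[k, ]), 0))
  }, 0))
  expect_gte(best, 0.9)
})

test_that("fractional expression follows its defining formula and sums to one", {
  A <- rbind(c(2, 0, 0), c(1, 1, 0))
  P <- rbind(rep(0.5, 4), rep(1.5, 4), rep(1, 4))  # r = (2, 6, 4)
  rownames(A) <- c("g1", "g2")
  decomp <- structure(list(A = A, P = P, K = 3), class = "pattern_decomposition")
  fe <- fractional_expression(decomp)
  expect_equal(unname(fe$f["g1", ]), c(1, 0, 0))
  expect_equal(unname(fe$f["g2", ]), c(2 / 8, 6 / 8, 0))  # A=(1,1,0), r=(2,6,4)
  # random decompositions: rows sum to 1 when expressed
  set.seed(6)
  decomp2 <- structure(list(A = matrix(runif(60), 20, 3),
                            P = matrix(runif(30), 3, 10), K = 3),
                       class = "pattern_decomposition")
  fe2 <- fractional_expression(decomp2)
  expect_equal(unname(rowSums(fe2$f)), rep(1, 20))
  # a silent gene is flagged, not divided by zero
  decomp2$A[1, ] <- 0
  fe3 <- fractional_expression(decomp2)
  expect_false(fe3$expressed[1])
  expect_true(all(is.na(fe3$f[1, ])))
})

test_that("marker statistic flags planted outliers and degenerate strata flag none", {
  # constructed: 3 strata x 3 patterns, tight background at 1/3
  set.seed(8)
  n_bg <- 120
  f_bg <- matrix(1 / 3 + runif(n_bg * 3, -0.02, 0.02), n_bg, 3)
  f_bg <- f_bg / rowSums(f_bg)
  f_mk <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05))
  f <- rbind(f_bg, f_mk)
  total <- c(runif(n_bg, 1, 100), 10, 50)
  rownames(f) <- sprintf("g%03d", seq_len(nrow(f)))
  colnames(f) <- paste0("pattern_", 1:3)
  fe <- list(f = f, total = total,
             expressed = rep(TRUE, nrow(f)))
  res <- pattern_marker_scores(fe)
  expect_true(res$marker[res$gene == "g121" & res$pattern == "pattern_1"])
  expect_true(res$marker[res$gene == "g122" & res$pattern == "pattern_2"])
  expect_false(any(res$marker[res$gene == "g121" & res$pattern != "pattern_1"]))
  # all-identical fractional expression: IQR = 0, no markers anywhere
  f0 <- matrix(1 / 3, 60, 3, dimnames = list(sprintf("h%02d", 1:60), NULL))
  fe0 <- list(f = f0, total = runif(60, 1, 10), expressed = rep(TRUE, 60))
  expect_false(any(pattern_marker_scores(fe0)$marker))
})

test_that("a dual-pattern gene is flagged as a marker of both patterns", {
  set.seed(9)
  n_bg <- 150
  f_bg <- matrix(1 / 3 + runif(n_bg * 3, -0.02, 0.02), n_bg, 3)
  f_bg <- f_bg / rowSums(f_bg)
  f <- rbind(f_bg, c(0.45, 0.45, 0.10))
  total <- runif(nrow(f), 1, 10)   # single effective stratum range
  rownames(f) <- sprintf("g%03d", seq_len(nrow(f)))
  colnames(f) <- paste0("pattern_", 1:3)
  res <- pattern_marker_scores(list(f = f, total = total,
                                    expressed = rep(TRUE, nrow(f))))
  dual <- res[res$gene == sprintf("g%03d", nrow(f)), ]
  expect_true(dual$marker[dual$pattern == "pattern_1"])
  expect_true(dual$marker[dual$pattern == "pattern_2"])
  expect_false(dual$marker[dual$pattern == "pattern_3"])
})

test_that("marker recovery on the full generator chain reaches F1 >= 0.9", {
  sim <- generate_spot_data(visium_sim_config(seed = 17))
  fit <- fit_nmf(log_transform(sim$spots$counts), K = 3, seed = 8)
  fe <- fractional_expression(fit)
  res <- pattern_marker_scores(fe)
  # map recovered patterns to planted ones by P correlation
  match_k <- vapply(1:3, function(k) {
    which.max(vapply(1:3, function(j) cor(fit$P[j, ], sim$truth$P_true[k, ]), 0))
  }, 0L)
  f1 <- vapply(1:3, function(k) {
    called <- res$gene[res$marker &
                         res$pattern == paste0("pattern_", match_k[k])]
    truth <- sim$truth$markers[[k]]
    tp <- length(intersect(called, truth))
    2 * tp / (length(called) + length(truth))
  }, 0)
  expect_gte(mean(f1), 0.9)
})

test_that("module scores are zero-centred for null signatures and idempotent to duplication", {
  sim <- generate_spot_data(visium_sim_config(seed = 23, delta = 0))
  D <- log_transform(sim$spots$counts)
  set.seed(10)
  sig <- sample(rownames(D), 15)
  ms <- module_score(D, sig, seed = 4)
  expect_lt(abs(mean(ms$score)), 0.05)
  ms_dup <- module_score(D, c(sig, sig), seed = 4)
  expect_equal(ms$score, ms_dup$score)
  expect_error(module_score(D, character(0)), "empty signature")
  expect_warning(module_score(D, c(sig, "nonexistent_gene"), seed = 4),
                 "missing")
})

test_that("planted signature elevation is recovered by the module score", {
  genes <- sprintf("g%03d", 1:400)
  A <- matrix(4, 400, 1, dimnames = list(genes, NULL))
  P <- matrix(1, 1, 500)
  set.seed(5)
  sig <- sample(genes, 12)
  cfg <- visium_sim_config(n_rows = 25, n_cols = 40, A_true = A, P_true = P,
                           signature_genes = sig, delta = 1,
                           tls_spots = 1:40, seed = 12)
  sim <- generate_spot_data(cfg)
  ms <- module_score(log_transform(sim$spots$counts), sig, seed = 2)
  is_tls <- startsWith(sim$spots$label, "TLS:")
  expect_equal(mean(ms$score[is_tls]) - mean(ms$score[!is_tls]), 1,
               tolerance = 0.1)
})

test_that("pattern-score correlation handles perfect, null, and planted cases", {
  x <- runif(50)
  res <- pattern_vs_module(x, 2 * x)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)
  expect_error(pattern_vs_module(rep(1, 10), runif(10)), "zero variance")
  # null: independent normals rarely show |r| > 0.1 at n = 1000
  set.seed(11)
  hits <- 0
  for (i in 1:100) {
    r <- pattern_vs_module(rnorm(1000), rnorm(1000))$r
    hits <- hits + (abs(r) < 0.1)
  }
  expect_gte(hits / 100, 0.95)
  # recovery: true r = 0.5
  set.seed(12)
  ok <- 0
  for (i in 1:200) {
    x <- rnorm(400)
    y <- x + rnorm(400, 0, sqrt(3))   # cor = 1/sqrt(1+3) = 0.5
    ok <- ok + (abs(pattern_vs_module(x, y)$r - 0.5) <= 0.1)
  }
  expect_gte(ok / 200, 0.9)
})

test_that("pattern weights across TLS classes: calibration, power, singleton handling", {
  set.seed(13)
  # null: three identical classes
  rej <- 0
  for (i in 1:400) {
    p <- compare_tls_classes(rnorm(60), rep(c("PanIN", "PDAC", "CP"), 20))$kruskal$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / 400, 0.02); expect_lte(rej / 400, 0.08)
  # power: one class shifted by 2 sd
  hits <- 0
  for (i in 1:100) {
    w <- c(rnorm(30), rnorm(30), rnorm(30, 2))
    hits <- hits + (compare_tls_classes(w, rep(c("a", "b", "c"), each = 30))$kruskal$p_value < 0.01)
  }
  expect_gte(hits / 100, 0.95)
  # singleton class excluded with warning
  expect_warning(res <- compare_tls_classes(c(rnorm(10), 5),
                                            c(rep(c("a", "b"), 5), "c")),
                 "singleton")
  expect_equal(nrow(res$pairwise), 1)
})
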