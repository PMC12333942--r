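# Independent brute-force oracles used across tests. These are written
# plainly (scalar loops, exhaustive enumeration) and never share code with
# the implementation they check.

# Minimum distance from one point to a polygon boundary, looping edges.
oracle_polygon_distance <- function(px, py, verts) {
  n <- nrow(verts)
  best <- Inf
  for (i in seq_len(n)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    j <- if (i == n) 1 else i + 1
    bx <- verts[j, 1]; by <- verts[j, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) 0 else ((px - ax) * dx + (py - ay) * dy) / len2
    t <- max(0, min(1, t))
    d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    best <- min(best, d)
  }
  best
}

# Winding-free even-odd inside test, scalar.
oracle_point_inside <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((verts[i, 2] > py) != (verts[j, 2] > py) &&
        px < (verts[j, 1] - verts[i, 1]) * (py - verts[i, 2]) /
          (verts[j, 2] - verts[i, 2]) + verts[i, 1]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# O(n^2) nearest-neighbour mean distances per ordered type pair
# (per-point scan over every candidate of the target type).
oracle_interaction_matrix <- function(cells, phenos) {
  k <- length(phenos)
  M <- matrix(NA_real_, k, k, dimnames = list(phenos, phenos))
  for (a in seq_len(k)) {
    ia <- which(cells$phenotype == phenos[a])
    for (b in seq_len(k)) {
      ib <- which(cells$phenotype == phenos[b])
      dists <- vapply(ia, function(i) {
        cand <- setdiff(ib, i)
        if (length(cand) == 0) return(Inf)
        min(sqrt((cells$x_um[i] - cells$x_um[cand])^2 +
                   (cells$y_um[i] - cells$y_um[cand])^2))
      }, 0)
      if (all(is.finite(dists))) M[a, b] <- mean(dists)
    }
  }
  M
}

# Brute-force top-2 neighbour counts with cell_id tie-break.
oracle_top2_matrix <- function(cells, phenos) {
  k <- length(phenos)
  N <- matrix(0L, k, k, dimnames = list(phenos, phenos))
  n <- nrow(cells)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 + (cells$y_um - cells$y_um[i])^2)
    d[i] <- Inf
    ord <- order(d, cells$cell_id)[1:2]
    fa <- match(cells$phenotype[i], phenos)
    for (j in ord) {
      fb <- match(cells$phenotype[j], phenos)
      N[fa, fb] <- N[fa, fb] + 1L
    }
  }
  N
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group-1 rank
# assignments (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- apply(combs, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Small default cell-map configuration for fast tests: one TLS of each
# maturity, two regions.
small_cell_config <- function(seed = 1) {
  regions <- data.frame(
    region_id = c("A", "B"), tissue_class = c("PanIN", "PDAC"),
    xmin = c(0, 2500), ymin = 0, xmax = c(1500, 4000), ymax = 1500)
  tls <- data.frame(center_x = c(500, 3000), center_y = c(500, 500),
                    radius_um = 120,
                    maturity = c("immature", "mature"), n_cells = 250)
  tissue_sim_config(regions = regions, tls_specs = tls, seed = seed)
}

# Phenotyped cell table from a config (full gating chain).
phenotype_cells <- function(sim) {
  ct <- transform_intensities(sim$cells)
  pos <- call_positivity(ct, thresholds = "bimodal")
  ct$phenotype <- apply_gates(pos, read_gates())
  ct
}
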