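# Cross nearest-neighbour distances: for each row of `from` (n x 2) the
# distance to the nearest row of `to` (m x 2). `self_map` gives, for rows of
# `from` that are also rows of `to`, their index in `to` (NA otherwise) so a
# cell never counts itself. Vectorised over the full cross-distance matrix;
# chunked over `from` to bound memory.
nn_distance <- function(from, to, self_map = NULL, chunk = 512L) {
  n <- nrow(from); m <- nrow(to)
  out <- numeric(n)
  to_sq <- to[, 1]^2 + to[, 2]^2
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f <- from[idx, , drop = FALSE]
    d2 <- outer(f[, 1]^2 + f[, 2]^2, to_sq, "+") -
      2 * (f %*% t(to))
    if (!is.null(self_map)) {
      sm <- self_map[idx]
      has <- which(!is.na(sm))
      d2[cbind(has, sm[has])] <- Inf
    }
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

retain_phenotypes <- function(cells, min_frac) {
  tab <- table(cells$phenotype)
  keep <- names(tab)[tab / nrow(cells) >= min_frac]
  sort(keep)
}

#' Average shortest-distance interaction matrix
#'
#' Entry (A, B) is the mean, over cells of type A, of the Euclidean
#' distance to the nearest cell of type B (self excluded on the diagonal).
#' Phenotypes making up less than `min_frac` of all cells are dropped
#' before computation, mirroring the <1% cluster exclusion used in the
#' original neighbourhood analysis. The matrix is asymmetric; it is
#' symmetrized only for network layout by [interaction_network()].
#'
#' @param cells Phenotyped cell table.
#' @param min_frac Minimum abundance fraction to retain a phenotype
#'   (default 0.01).
#' @return Object of class `interaction_matrix`: list with `M` (um),
#'   `abundance` (cells per retained phenotype), `phenotypes`.
#' @export
interaction_matrix <- function(cells, min_frac = 0.01) {
  if (nrow(cells) < 2) stop("need >= 2 cells")
  if (min_frac < 0 || min_frac >= 1) stop("min_frac must be in [0,1)")
  phenos <- retain_phenotypes(cells, min_frac)
  xy <- split(seq_len(nrow(cells)), cells$phenotype)[phenos]
  coords <- cbind(cells$x_um, cells$y_um)
  k <- length(phenos)
  M <- matrix(NA_real_, k, k, dimnames = list(phenos, phenos))
  for (b in seq_len(k)) {
    to_idx <- xy[[b]]
    to <- coords[to_idx, , drop = FALSE]
    for (a in seq_len(k)) {
      from_idx <- xy[[a]]
      if (a == b && length(from_idx) == 1) {
        message("phenotype '", phenos[a],
                "' has a single cell; diagonal entry left missing")
        next
      }
      self_map <- if (a == b) seq_along(from_idx) else NULL
      d <- nn_distance(coords[from_idx, , drop = FALSE], to, self_map)
      M[a, b] <- mean(d)
    }
  }
  structure(list(M = M,
                 abundance = lengths(xy),
                 phenotypes = phenos),
            class = "interaction_matrix")
}

#' Interaction network edge list
#'
#' Undirected edges between retained phenotypes with length equal to the
#' symmetrized mean shortest distance (M[A,B] + M[B,A]) / 2; node weight is
#' phenotype abundance.
#'
#' @param im An [interaction_matrix()] result.
#' @return List with `edges` (source, target, mean_distance_um) and
#'   `nodes` (phenotype, n_cells) data frames.
#' @export
interaction_network <- function(im) {
  stopifnot(inherits(im, "interaction_matrix"))
  ph <- im$phenotypes
  pairs <- which(upper.tri(im$M, diag = TRUE), arr.ind = TRUE)
  edges <- data.frame(
    source = ph[pairs[, 1]],
    target = ph[pairs[, 2]],
    mean_distance_um = (im$M[pairs] + t(im$M)[pairs]) / 2
  )
  nodes <- data.frame(phenotype = ph, n_cells = as.integer(im$abundance))
  list(edges = edges[!is.na(edges$mean_distance_um), ], nodes = nodes)
}

#' Top-2 nearest-neighbour contact matrix
#'
#' For each cell, its two nearest other cells (Euclidean distance, ties
#' broken by smaller `cell_id`) each add one count to
#' N[type(cell), type(neighbour)]. Row sums therefore equal 2 x the number
#' of cells of the focal type. Phenotypes below `min_frac` abundance are
#' excluded before neighbour finding.
#'
#' @param cells Phenotyped cell table with `cell_id`.
#' @param min_frac Minimum abundance fraction (default 0.01).
#' @return Integer matrix (focal type x neighbour type) of class
#'   `neighbor_contacts`.
#' @export
top2_neighbor_matrix <- function(cells, min_frac = 0.01) {
  phenos <- retain_phenotypes(cells, min_frac)
  cells <- cells[cells$phenotype %in% phenos, , drop = FALSE]
  n <- nrow(cells)
  if (n < 3) stop("need >= 3 cells after exclusion")
  coords <- cbind(cells$x_um, cells$y_um)
  ids <- cells$cell_id
  k <- length(phenos)
  N <- matrix(0L, k, k, dimnames = list(phenos, phenos))
  type_idx <- match(cells$phenotype, phenos)
  chunk <- 512L
  sq <- coords[, 1]^2 + coords[, 2]^2
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * (coords[idx, , drop = FALSE] %*% t(coords))
    d2[cbind(seq_along(idx), idx)] <- Inf
    for (i in seq_along(idx)) {
      ord <- order(d2[i, ], ids)[1:2]
      for (j in ord) {
        N[type_idx[idx[i]], type_idx[j]] <- N[type_idx[idx[i]], type_idx[j]] + 1L
      }
    }
  }
  structure(N, class = c("neighbor_contacts", class(N)))
}

#' Normalize a contact matrix by the dominant phenotype count
#'
#' Divides every entry by the cell count of the most abundant phenotype in
#' the region's cells (flag `denominator = "max_entry"` divides by the
#' largest matrix entry instead).
#'
#' @param N Contact matrix from [top2_neighbor_matrix()].
#' @param region_cells Cell table of the region the matrix was computed on.
#' @param denominator `"max_phenotype"` (default) or `"max_entry"`.
#' @return Numeric matrix of normalized contact frequencies.
#' @export
normalize_contacts <- function(N, region_cells,
                               denominator = c("max_phenotype", "max_entry")) {
  denominator <- match.arg(denominator)
  if (nrow(region_cells) < 1) stop("region has no cells")
  div <- if (denominator == "max_phenotype") {
    max(table(region_cells$phenotype))
  } else {
    max(N)
  }
  unclass(N) / div
}
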