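#' Spot-level expression container
#'
#' Bundles a gene x spot count matrix on a hex lattice with per-spot array
#' coordinates, tissue-composition fractions, segment membership, and a
#' spot label (`TLS:<id>`, `TLS_neighbor`, `other`).
#'
#' @param counts Gene x spot matrix of non-negative integer counts
#'   (dense or `Matrix` sparse), with rownames (genes) and colnames
#'   (barcodes).
#' @param positions Data frame with columns `barcode`, `array_row`,
#'   `array_col`, `x_um`, `y_um`, one row per spot, in column order of
#'   `counts`.
#' @param composition Optional data frame (spots x tissue classes) of
#'   fractions; per-spot sums may be below 1, the remainder being
#'   non-tissue.
#' @param segment_id Optional per-spot segment identifier.
#' @return Object of class `spot_matrix`.
#' @export
spot_matrix <- function(counts, positions, composition = NULL,
                        segment_id = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  n_spots <- ncol(counts)
  if (nrow(positions) != n_spots) stop("positions do not match counts columns")
  if (!all(positions$barcode == colnames(counts)))
    stop("positions barcodes must match counts colnames in order")
  if (any((positions$array_row + positions$array_col) %% 2 != 0))
    stop("spots must satisfy the even (row + col) hex-array convention")
  if (!is.null(composition)) {
    if (nrow(composition) != n_spots) stop("composition rows != spots")
    if (any(rowSums(composition) > 1 + 1e-9))
      stop("composition fractions exceed 1")
  }
  if (is.null(segment_id)) segment_id <- rep("segment1", n_spots)
  structure(list(counts = counts,
                 genes = rownames(counts),
                 barcodes = colnames(counts),
                 positions = positions,
                 composition = composition,
                 segment_id = as.character(segment_id),
                 label = rep("other", n_spots)),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat("spot_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "spots;",
      length(unique(x$segment_id)), "segment(s)\n")
  invisible(x)
}

subset_spots <- function(spots, keep) {
  spots$counts <- spots$counts[, keep, drop = FALSE]
  spots$barcodes <- spots$barcodes[keep]
  spots$positions <- spots$positions[keep, , drop = FALSE]
  if (!is.null(spots$composition))
    spots$composition <- spots$composition[keep, , drop = FALSE]
  spots$segment_id <- spots$segment_id[keep]
  spots$label <- spots$label[keep]
  spots
}

#' Quality filter for spots and segments
#'
#' Three rules, applied in order and logged: (1) each spot is labelled by
#' its predominant tissue class when that class reaches
#' `min_tissue_frac` of the spot, else left unlabelled (mixed); (2) spots
#' whose tissue label is in `drop_classes` (fat by default, where probe
#' bleed-over from acinar tissue inflates RNA-poor adipocyte regions) or
#' whose non-tissue fraction reaches `min_tissue_frac` are removed;
#' (3) whole segments whose median per-spot UMI count falls below
#' `min_segment_median_umi` are removed.
#'
#' @param spots A [spot_matrix()] with composition.
#' @param min_tissue_frac Predominance threshold (default 0.70).
#' @param drop_classes Tissue classes removed outright.
#' @param min_segment_median_umi Minimum segment median UMI (default 200).
#' @return Filtered `spot_matrix` with a per-spot `tissue_class` entry and
#'   an attribute `removed` (data frame barcode/reason).
#' @export
filter_spots <- function(spots, min_tissue_frac = 0.70,
                         drop_classes = "fat",
                         min_segment_median_umi = 200) {
  stopifnot(inherits(spots, "spot_matrix"))
  if (is.null(spots$composition)) stop("composition required")
  comp <- as.matrix(spots$composition)
  top <- max.col(comp, ties.method = "first")
  top_frac <- comp[cbind(seq_len(nrow(comp)), top)]
  tissue_class <- ifelse(top_frac >= min_tissue_frac,
                         colnames(comp)[top], NA_character_)
  non_tissue <- pmax(0, 1 - rowSums(comp))
  umi <- Matrix::colSums(spots$counts)
  seg_median <- tapply(umi, spots$segment_id, stats::median)
  low_segment <- spots$segment_id %in%
    names(seg_median)[seg_median < min_segment_median_umi]
  reason <- rep(NA_character_, ncol(spots$counts))
  reason[!is.na(tissue_class) & tissue_class %in% drop_classes] <-
    "dropped tissue class"
  reason[is.na(reason) & non_tissue >= min_tissue_frac] <- "non-tissue"
  reason[is.na(reason) & low_segment] <- "low-UMI segment"
  removed <- data.frame(barcode = spots$barcodes[!is.na(reason)],
                        reason = reason[!is.na(reason)])
  if (nrow(removed)) {
    message("filter_spots: removing ", nrow(removed), " spot(s) (",
            paste(sprintf("%s: %d", names(table(removed$reason)),
                          as.integer(table(removed$reason))),
                  collapse = "; "), ")")
  }
  keep <- is.na(reason)
  out <- subset_spots(spots, keep)
  out$tissue_class <- tissue_class[keep]
  if (ncol(out$counts) == 0) message("filter_spots: no spots survive filtering")
  attr(out, "removed") <- removed
  out
}

#' Label spots as TLS, TLS neighbourhood, or other
#'
#' Spots whose centre falls inside a TLS hull get `TLS:<id>` (a spot under
#' overlapping hulls is assigned to the hull with the nearest centroid,
#' with a message); spots within `depth` hex-lattice steps of any TLS spot
#' (but not themselves TLS) get `TLS_neighbor`; the rest `other`. The
#' labels partition the retained spots.
#'
#' @param spots A `spot_matrix` (typically after [filter_spots()]).
#' @param tls_hulls List of `tls_record`s (or any objects with `tls_id`,
#'   `hull`, `centroid`).
#' @param depth Neighbourhood expansion depth in lattice steps (default 2).
#' @return The `spot_matrix` with its `label` field set.
#' @export
label_tls_spots <- function(spots, tls_hulls, depth = 2) {
  stopifnot(inherits(spots, "spot_matrix"))
  if (depth < 1) stop("depth must be >= 1")
  n <- ncol(spots$counts)
  pts <- cbind(spots$positions$x_um, spots$positions$y_um)
  label <- rep("other", n)
  hit_count <- integer(n)
  hit_dist <- rep(Inf, n)
  for (h in tls_hulls) {
    poly <- region_polygon(paste0("tls", h$tls_id), "TLS", h$hull)
    inside <- signed_boundary_distance(pts, poly) <= 0
    cd <- sqrt((pts[, 1] - h$centroid[1])^2 + (pts[, 2] - h$centroid[2])^2)
    claim <- inside & (hit_count == 0 | cd < hit_dist)
    label[claim] <- paste0("TLS:", h$tls_id)
    hit_dist[inside & cd < hit_dist] <- cd[inside & cd < hit_dist]
    hit_count <- hit_count + inside
  }
  if (any(hit_count > 1)) {
    message(sum(hit_count > 1),
            " spot(s) under overlapping hulls assigned to nearest centroid")
  }
  is_tls <- startsWith(label, "TLS:")
  if (any(is_tls)) {
    nb <- spot_neighbors(spots$positions,
                         spots$positions[is_tls, c("array_row", "array_col")],
                         depth = depth)
    nb_key <- hex_key(nb$array_row, nb$array_col)
    spot_key <- hex_key(spots$positions$array_row, spots$positions$array_col)
    label[!is_tls & spot_key %in% nb_key] <- "TLS_neighbor"
  }
  spots$label <- label
  spots
}

#' Log2 transform with pseudocount
#'
#' `D = log2(counts + 1)`, the input scale for the pattern decomposition.
#'
#' @param counts Non-negative matrix (dense or sparse).
#' @return Dense numeric matrix.
#' @export
log_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log2(counts + 1)
}

#' Library-size normalized log expression
#'
#' `log2(CP10K + 1)`: counts scaled to 10,000 per spot, then log2 with
#' pseudocount. Used for module scoring.
#'
#' @param counts Gene x spot count matrix.
#' @return Dense numeric matrix.
#' @export
normalize_cp10k <- function(counts) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("spot with zero total counts")
  log2(sweep(counts, 2, 1e4 / libsize, "*") + 1)
}
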