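write_manifest <- function(out_dir, files) {
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run the proteomic (cell-map) analysis arm
#'
#' Chains phenotyping (asinh transform, positivity, gates), per-region
#' densities with pairwise Wilcoxon tests, interaction and top-2
#' neighbour contact matrices, and TLS detection / association /
#' maturity classification. All tables are written as CSV under
#' `out_dir` with a checksum manifest.
#'
#' @param cells Raw cell table (cell_id, x_um, y_um, region_id, marker
#'   columns).
#' @param regions List of [region_polygon()]s.
#' @param out_dir Output directory.
#' @param gates Gating rules; default the packaged panel.
#' @param thresholds Positivity thresholds passed to [call_positivity()];
#'   default `"bimodal"` (per-marker 2-means split).
#' @param min_frac Phenotype abundance cutoff for interaction analyses.
#' @param band_um TLS-lesion association cutoff (default 250).
#' @param eps_um,min_samples,min_cells Aggregate detection parameters.
#' @return Invisibly, a list with the phenotyped cells, density table,
#'   tls table, and manifest path.
#' @export
run_proteomic_arm <- function(cells, regions, out_dir,
                              gates = read_gates(), thresholds = "bimodal",
                              min_frac = 0.01, band_um = 250,
                              eps_um = 30, min_samples = 10,
                              min_cells = 50) {
  if (nrow(cells) == 0) stop("empty cell table: nothing to analyse")
  missing_mk <- setdiff(unlist(lapply(gates, function(g)
    c(g$positive, g$negative))), marker_columns(cells))
  if (length(missing_mk)) {
    stop("gate panel references marker(s) absent from the cell table: ",
         paste(missing_mk, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells_t <- transform_intensities(cells)
  pos <- call_positivity(cells_t, thresholds = thresholds)
  cells_t$phenotype <- apply_gates(pos, gates)

  dens <- cell_density(cells_t, regions)
  classes <- unique(dens$tissue_class)
  tests <- list()
  if (length(classes) >= 2) {
    pairs <- utils::combn(sort(classes), 2)
    for (ph in unique(dens$phenotype)) {
      for (j in seq_len(ncol(pairs))) {
        sub <- dens[dens$phenotype == ph &
                      dens$tissue_class %in% pairs[, j], ]
        counts <- table(sub$tissue_class)
        if (length(counts) < 2 || any(counts < 2)) next
        res <- compare_groups(sub$density, sub$tissue_class, "wilcoxon")
        tests[[length(tests) + 1]] <- data.frame(
          phenotype = ph, group1 = pairs[1, j], group2 = pairs[2, j],
          statistic = res$statistic, p_value = res$p_value)
      }
    }
  }
  test_tab <- if (length(tests)) do.call(rbind, tests) else
    data.frame(phenotype = character(0), group1 = character(0),
               group2 = character(0), statistic = numeric(0),
               p_value = numeric(0))

  im <- interaction_matrix(cells_t, min_frac = min_frac)
  net <- interaction_network(im)
  contacts <- top2_neighbor_matrix(cells_t, min_frac = min_frac)
  contacts_norm <- normalize_contacts(contacts, cells_t)

  tls_list <- detect_aggregates(cells_t, eps_um = eps_um,
                                min_samples = min_samples,
                                min_cells = min_cells)
  tls_list <- lapply(tls_list, associate_tls, regions = regions,
                     max_dist_um = band_um)
  tls_tab <- if (length(tls_list)) tls_table(tls_list, cells_t) else
    data.frame()

  files <- c(file.path(out_dir, "phenotyped_cells.csv"),
             file.path(out_dir, "density.csv"),
             file.path(out_dir, "density_tests.csv"),
             file.path(out_dir, "interaction_matrix.csv"),
             file.path(out_dir, "interaction_edges.csv"),
             file.path(out_dir, "contacts.csv"),
             file.path(out_dir, "contacts_normalized.csv"),
             file.path(out_dir, "tls_table.csv"))
  utils::write.csv(cells_t, files[1], row.names = FALSE)
  utils::write.csv(dens, files[2], row.names = FALSE)
  utils::write.csv(test_tab, files[3], row.names = FALSE)
  utils::write.csv(as.data.frame(im$M), files[4])
  utils::write.csv(net$edges, files[5], row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(contacts)), files[6])
  utils::write.csv(as.data.frame(contacts_norm), files[7])
  utils::write.csv(tls_tab, files[8], row.names = FALSE)
  manifest <- write_manifest(out_dir, files)
  invisible(list(cells = cells_t, density = dens, density_tests = test_tab,
                 interaction = im, contacts = contacts, tls = tls_list,
                 tls_table = tls_tab, manifest = manifest))
}

#' Run the transcriptomic (spot-level) analysis arm
#'
#' Chains spot QC (when composition is present), TLS labelling with
#' depth-limited neighbour expansion, log2 transform, sparse NMF, the
#' fractional-expression pattern-marker statistic, module scoring against
#' a signature, pattern-vs-score correlation, pattern-weight class
#' comparisons, and preranked GSEA per pattern. Tables are written under
#' `out_dir` with a checksum manifest.
#'
#' @param spots A [spot_matrix()].
#' @param out_dir Output directory.
#' @param tls_hulls Optional list of TLS hull records for
#'   [label_tls_spots()]; when `NULL`, existing `TLS:` labels on the
#'   object are kept and only the neighbour expansion is applied.
#' @param signature Signature gene vector for module scoring.
#' @param gene_sets Optional named list (or GMT path) for GSEA.
#' @param K Number of patterns.
#' @param alpha NMF sparsity penalty.
#' @param depth Neighbour expansion depth (default 2).
#' @param seed Integer seed.
#' @param n_perm GSEA permutations.
#' @param tls_only Fit the NMF on TLS + neighbour spots only (default
#'   TRUE, matching the analysis design; FALSE uses all spots).
#' @return Invisibly, a list with the decomposition, marker table, module
#'   scores, statistics, GSEA table, and manifest path.
#' @export
run_transcriptomic_arm <- function(spots, out_dir, tls_hulls = NULL,
                                   signature, gene_sets = NULL, K = 3,
                                   alpha = 0.01, depth = 2, seed = 1,
                                   n_perm = 1000, tls_only = TRUE) {
  stopifnot(inherits(spots, "spot_matrix"))
  if (depth < 1) stop("depth must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(spots$composition)) spots <- filter_spots(spots)
  if (ncol(spots$counts) == 0) stop("all spots filtered out")
  if (!is.null(tls_hulls)) {
    spots <- label_tls_spots(spots, tls_hulls, depth = depth)
  } else if (any(startsWith(spots$label, "TLS:"))) {
    seeds <- spots$positions[startsWith(spots$label, "TLS:"),
                             c("array_row", "array_col")]
    nb <- spot_neighbors(spots$positions, seeds, depth = depth)
    key <- hex_key(spots$positions$array_row, spots$positions$array_col)
    nb_key <- hex_key(nb$array_row, nb$array_col)
    spots$label[!startsWith(spots$label, "TLS:") & key %in% nb_key] <-
      "TLS_neighbor"
  }
  fit_idx <- if (tls_only && any(spots$label != "other")) {
    which(spots$label != "other")
  } else {
    seq_len(ncol(spots$counts))
  }
  D <- log_transform(spots$counts[, fit_idx, drop = FALSE])
  decomp <- fit_nmf(D, K = K, alpha = alpha, seed = seed)
  fe <- fractional_expression(decomp)
  markers <- pattern_marker_scores(fe)

  D_norm <- normalize_cp10k(spots$counts)
  ms <- module_score(D_norm, signature, seed = seed)
  is_tls <- startsWith(spots$label, "TLS:")
  weights_full <- matrix(NA_real_, K, ncol(spots$counts),
                         dimnames = list(rownames(decomp$P), spots$barcodes))
  weights_full[, fit_idx] <- decomp$P
  # TLS-coupled pattern: highest mean weight over TLS spots in the fit
  tls_in_fit <- is_tls[fit_idx]
  tls_pattern <- if (any(tls_in_fit)) {
    unname(which.max(rowMeans(decomp$P[, tls_in_fit, drop = FALSE])))
  } else {
    1L
  }
  corr <- pattern_vs_module(decomp$P[tls_pattern, ], ms$score[fit_idx])
  cls <- ifelse(is_tls[fit_idx], "TLS", spots$label[fit_idx])
  class_cmp <- if (length(unique(cls)) >= 2 && min(table(cls)) >= 2) {
    compare_tls_classes(decomp$P[tls_pattern, ], cls)
  } else {
    NULL
  }
  gsea_tab <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets) && length(gene_sets) == 1) {
      gene_sets <- read_gmt(gene_sets)
    }
    gsea_tab <- do.call(rbind, lapply(seq_len(K), function(k) {
      mk <- markers[markers$pattern == rownames(decomp$P)[k], ]
      z <- stats::setNames(mk$z, mk$gene)
      res <- gsea_preranked(z, gene_sets, n_perm = n_perm, seed = seed)
      if (nrow(res)) res$pattern <- rownames(decomp$P)[k]
      res
    }))
  }

  files <- c(file.path(out_dir, "pattern_weights.csv"),
             file.path(out_dir, "pattern_amplitudes.csv"),
             file.path(out_dir, "marker_table.csv"),
             file.path(out_dir, "module_scores.csv"),
             file.path(out_dir, "pattern_stats.csv"),
             file.path(out_dir, "spot_labels.csv"))
  utils::write.csv(data.frame(barcode = spots$barcodes, t(weights_full)),
                   files[1], row.names = FALSE)
  utils::write.csv(data.frame(gene = rownames(decomp$A), decomp$A),
                   files[2], row.names = FALSE)
  utils::write.csv(markers, files[3], row.names = FALSE)
  utils::write.csv(data.frame(barcode = spots$barcodes, score = ms$score),
                   files[4], row.names = FALSE)
  stats_tab <- data.frame(quantity = c("tls_pattern", "pearson_r",
                                       "r_squared", "pearson_p",
                                       "kruskal_p"),
                          value = c(tls_pattern, corr$r, corr$r_squared,
                                    corr$p_value,
                                    if (is.null(class_cmp)) NA else
                                      class_cmp$kruskal$p_value))
  utils::write.csv(stats_tab, files[5], row.names = FALSE)
  utils::write.csv(data.frame(barcode = spots$barcodes, label = spots$label),
                   files[6], row.names = FALSE)
  if (!is.null(gsea_tab)) {
    files <- c(files, file.path(out_dir, "gsea.csv"))
    utils::write.csv(gsea_tab, files[length(files)], row.names = FALSE)
  }
  if (!is.null(class_cmp)) {
    files <- c(files, file.path(out_dir, "pairwise_tests.csv"))
    utils::write.csv(class_cmp$pairwise, files[length(files)],
                     row.names = FALSE)
  }
  manifest <- write_manifest(out_dir, files)
  invisible(list(spots = spots, decomposition = decomp, markers = markers,
                 module_scores = ms, tls_pattern = tls_pattern,
                 correlation = corr, class_comparison = class_cmp,
                 gsea = gsea_tab, manifest = manifest))
}
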