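NON_MARKER_COLS <- c("cell_id", "x_um", "y_um", "region_id",
                     "cluster_id", "phenotype")

#' Marker columns of a cell table
#'
#' Every column that is not one of the reserved bookkeeping columns
#' (`cell_id`, `x_um`, `y_um`, `region_id`, `cluster_id`, `phenotype`)
#' is treated as a marker intensity.
#'
#' @param cells Cell table data.frame.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(cells) {
  setdiff(colnames(cells), NON_MARKER_COLS)
}

#' Variance-stabilizing transform of marker intensities
#'
#' Applies `asinh(x / cofactor)` to every marker column, the standard
#' mass-cytometry transform. Order-preserving; zero maps to zero.
#'
#' @param cells Cell table with non-negative raw intensities.
#' @param cofactor Positive cofactor; 5 is the mass-cytometry convention.
#' @return The cell table with marker columns transformed; a
#'   `transformed` attribute records the cofactor.
#' @export
transform_intensities <- function(cells, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be > 0")
  mk <- marker_columns(cells)
  for (m in mk) {
    if (any(cells[[m]] < 0)) stop("negative intensity in marker ", m)
    cells[[m]] <- asinh(cells[[m]] / cofactor)
  }
  attr(cells, "transformed") <- cofactor
  cells
}

#' Marker positivity calls
#'
#' A cell is positive for a marker when its (transformed) intensity exceeds
#' the marker's threshold. Thresholds are either supplied per marker or
#' computed as a per-marker quantile over all cells (type-7 quantiles,
#' i.e. linear interpolation). A constant marker column in quantile mode
#' yields a threshold at that constant, so no cell is called positive.
#'
#' Intensity distributions of rare phenotypes' markers are far from any
#' fixed quantile, so a third mode, `thresholds = "bimodal"`, estimates
#' each marker's threshold as the midpoint of a deterministic 1-D 2-means
#' split (initialized at the data extremes) — robust to the positive
#' fraction as long as the marker is bimodal.
#'
#' @param cells Cell table, normally after [transform_intensities()].
#' @param thresholds Named numeric vector of per-marker thresholds on the
#'   same scale as the table, the string `"bimodal"`, or `NULL` to use
#'   quantile mode.
#' @param q Quantile in (0,1) for quantile mode; default 0.75.
#' @return Logical matrix (cells x markers) with a `thresholds` attribute.
#' @export
call_positivity <- function(cells, thresholds = NULL, q = 0.75) {
  mk <- marker_columns(cells)
  x <- as.matrix(cells[, mk, drop = FALSE])
  if (is.null(thresholds)) {
    if (q <= 0 || q >= 1) stop("q must be in (0,1)")
    thresholds <- apply(x, 2, stats::quantile, probs = q, names = FALSE)
  } else if (identical(thresholds, "bimodal")) {
    thresholds <- apply(x, 2, bimodal_threshold)
  } else {
    missing <- setdiff(mk, names(thresholds))
    if (length(missing)) stop("no threshold for marker(s): ",
                              paste(missing, collapse = ", "))
    thresholds <- thresholds[mk]
  }
  pos <- sweep(x, 2, thresholds, ">")
  dimnames(pos) <- list(NULL, mk)
  attr(pos, "thresholds") <- thresholds
  pos
}

# Per-marker positivity threshold by density-valley gating on log
# intensities: kernel density estimate, then the first deep valley to the
# right of the dominant (negative) mode. A valley qualifies when density
# drops below half of both the main mode and the best mode beyond the
# valley, and that mode carries non-negligible mass (`min_height` of the
# peak) — this rejects shoulder wiggles on the bulk and sparse far-tail
# bumps alike, and works whether 2% or 40% of cells are positive. A
# marker with no qualifying positive mode gets threshold = max, so the
# strict `>` comparison calls no cell positive.
bimodal_threshold <- function(v, min_height = 0.008) {
  if (min(v) == max(v)) return(min(v))
  pos <- v[v > 0]
  if (length(pos) == 0) return(max(v))
  lv <- log(pmax(v, min(pos) / 2))
  d <- stats::density(lv, n = 1024)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) < 0) + 1
  loc_min <- which(diff(sign(diff(y))) > 0) + 1
  if (length(loc_max) < 2) return(max(v))
  main <- loc_max[which.max(y[loc_max])]
  for (vl in loc_min[loc_min > main]) {
    beyond <- loc_max[loc_max > vl]
    if (length(beyond) == 0) break
    peak <- max(y[beyond])
    if (peak >= min_height * max(y) &&
        y[vl] < 0.5 * peak && y[vl] < 0.5 * y[main]) {
      return(exp(d$x[vl]))
    }
  }
  max(v)
}

#' Define a phenotype gate
#'
#' @param name Phenotype label.
#' @param positive Markers that must be positive.
#' @param negative Markers that must be negative; disjoint from `positive`.
#' @return A `gating_rule` object.
#' @export
gating_rule <- function(name, positive, negative = character(0)) {
  positive <- as.character(positive); negative <- as.character(negative)
  if (length(intersect(positive, negative)))
    stop("a marker cannot be both required-positive and required-negative")
  structure(list(name = name, positive = positive, negative = negative),
            class = "gating_rule")
}

# More specific rules (more markers constrained) fire first; ties keep
# declaration order.
order_gates <- function(rules) {
  spec <- vapply(rules, function(r) length(r$positive) + length(r$negative), 0L)
  rules[order(-spec, seq_along(rules))]
}

#' Assign phenotypes by ordered boolean gates
#'
#' Rules are ranked by specificity (number of constrained markers,
#' declaration order breaking ties); the first rule whose required-positive
#' markers are all positive and required-negative markers all negative
#' claims the cell. Unmatched cells get `"unassigned"`.
#'
#' @param pos_matrix Logical matrix from [call_positivity()].
#' @param rules List of [gating_rule()] objects.
#' @return Character vector of phenotype labels, one per row.
#' @export
apply_gates <- function(pos_matrix, rules) {
  markers <- colnames(pos_matrix)
  for (r in rules) {
    unknown <- setdiff(c(r$positive, r$negative), markers)
    if (length(unknown)) stop("gate '", r$name, "' references unknown marker(s): ",
                              paste(unknown, collapse = ", "))
  }
  rules <- order_gates(rules)
  label <- rep("unassigned", nrow(pos_matrix))
  open <- rep(TRUE, nrow(pos_matrix))
  for (r in rules) {
    hit <- open
    for (m in r$positive) hit <- hit & pos_matrix[, m]
    for (m in r$negative) hit <- hit & !pos_matrix[, m]
    label[hit] <- r$name
    open <- open & !hit
  }
  label
}

#' Load gate definitions from a YAML file
#'
#' The file is a list of entries with `name`, `positive`, and optional
#' `negative` fields. The packaged default panel
#' (`system.file("extdata", "gates.yaml", package = "tlscape")`) encodes the
#' immune and structural phenotypes used throughout the analysis, e.g.
#' Tregs as CD3+CD4+FOXP3+PD1- and germinal-center B cells as
#' CD20+CD21+CD23+.
#'
#' @param path YAML file; defaults to the packaged panel.
#' @return List of `gating_rule` objects.
#' @export
read_gates <- function(path = system.file("extdata", "gates.yaml",
                                          package = "tlscape")) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(d) {
    gating_rule(d$name, unlist(d$positive),
                if (is.null(d$negative)) character(0) else unlist(d$negative))
  })
}

#' Cluster cells on transformed marker intensities
#'
#' k-means with a fixed seed; a deterministic, desk-scale stand-in for
#' self-organizing-map or graph-based cytometry clustering.
#'
#' @param cells Cell table after [transform_intensities()].
#' @param k Number of clusters, 2 <= k <= number of cells.
#' @param seed Integer seed.
#' @param nstart Random restarts for k-means.
#' @return Integer vector of cluster ids (1..k).
#' @export
cluster_cells <- function(cells, k, seed = 1, nstart = 5) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(cells)) stop("k exceeds number of cells")
  x <- as.matrix(cells[, marker_columns(cells), drop = FALSE])
  set.seed(seed)
  stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)$cluster
}

#' Annotate clusters with gate phenotypes
#'
#' A cluster is called positive for a marker when at least `frac_positive`
#' of its cells are positive; the gates are then applied to these
#' cluster-level calls.
#'
#' @param pos_matrix Per-cell positivity matrix from [call_positivity()].
#' @param cluster_ids Cluster assignment per cell.
#' @param rules Gating rules.
#' @param frac_positive Fraction of positive cells needed to call a cluster
#'   positive for a marker (default 0.5).
#' @return Named character vector: phenotype per cluster id.
#' @export
annotate_clusters <- function(pos_matrix, cluster_ids, rules,
                              frac_positive = 0.5) {
  ids <- sort(unique(cluster_ids))
  cluster_pos <- t(vapply(ids, function(cl) {
    colMeans(pos_matrix[cluster_ids == cl, , drop = FALSE]) >= frac_positive
  }, logical(ncol(pos_matrix))))
  colnames(cluster_pos) <- colnames(pos_matrix)
  labels <- apply_gates(cluster_pos, rules)
  stats::setNames(labels, ids)
}
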