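#' Per-region phenotype densities
#'
#' Density is the number of cells of a phenotype in a region divided by the
#' region's tissue area (cells per mm^2). Every (region, phenotype) pair is
#' reported, including zero counts and the `unassigned` bucket, so counts
#' sum to the number of cells per region.
#'
#' @param cells Phenotyped cell table (column `phenotype`, `region_id`).
#' @param regions List of [region_polygon()] objects covering every
#'   `region_id` in `cells`.
#' @return Data frame: `region_id`, `tissue_class`, `phenotype`, `count`,
#'   `area_mm2`, `density` (cells/mm^2).
#' @export
cell_density <- function(cells, regions) {
  ids <- vapply(regions, function(r) r$region_id, "")
  if (anyDuplicated(ids)) stop("duplicate region_id in region set")
  areas <- vapply(regions, function(r) r$area_mm2, 0)
  classes <- vapply(regions, function(r) r$tissue_class, "")
  if (any(areas <= 0)) stop("zero-area region")
  unknown <- setdiff(unique(cells$region_id), ids)
  if (length(unknown)) stop("cells reference unknown region(s): ",
                            paste(unknown, collapse = ", "))
  phenos <- sort(unique(cells$phenotype))
  out <- expand.grid(region_id = ids, phenotype = phenos,
                     stringsAsFactors = FALSE)
  tab <- table(factor(cells$region_id, levels = ids),
               factor(cells$phenotype, levels = phenos))
  out$count <- as.integer(tab[cbind(out$region_id, out$phenotype)])
  out$tissue_class <- classes[match(out$region_id, ids)]
  out$area_mm2 <- areas[match(out$region_id, ids)]
  out$density <- out$count / out$area_mm2
  out[, c("region_id", "tissue_class", "phenotype",
          "count", "area_mm2", "density")]
}

#' Density ratio of two phenotypes per region
#'
#' E.g. the CD8 T cell to Treg ratio. A zero denominator yields `NA`
#' (with a warning), never infinity.
#'
#' @param records Output of [cell_density()].
#' @param numerator,denominator Phenotype names.
#' @return Data frame `region_id`, `tissue_class`, `ratio`.
#' @export
density_ratio <- function(records, numerator, denominator) {
  for (p in c(numerator, denominator)) {
    if (!p %in% records$phenotype) stop("unknown phenotype: ", p)
  }
  num <- records[records$phenotype == numerator, ]
  den <- records[records$phenotype == denominator, ]
  den <- den[match(num$region_id, den$region_id), ]
  ratio <- ifelse(den$density > 0, num$density / den$density, NA_real_)
  if (anyNA(ratio)) {
    warning("denominator phenotype absent in ",
            sum(is.na(ratio)), " region(s); ratio set to NA")
  }
  data.frame(region_id = num$region_id, tissue_class = num$tissue_class,
             ratio = ratio)
}

# TRUE when the exact rank-sum distribution applies: both groups small and
# no tied values.
wilcoxon_exact_mode <- function(x, y, n_exact = 12) {
  length(x) <= n_exact && length(y) <= n_exact && !anyDuplicated(c(x, y))
}

#' Two-group and multi-group rank tests
#'
#' Wilcoxon rank-sum (two-sided) for two groups — exact enumeration when
#' both groups have at most 12 observations and no ties, otherwise the
#' normal approximation with tie and continuity corrections — and
#' Kruskal-Wallis (chi-square approximation with tie correction) for
#' several groups. No multiple-testing adjustment is applied here; density
#' comparisons are reported unadjusted, mirroring how such panels are
#' usually presented, and callers can adjust downstream.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param test `"wilcoxon"` (exactly 2 groups) or `"kruskal"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values, groups, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 1)) stop("empty group")
  if (test == "wilcoxon") {
    if (length(split_vals) != 2) stop("wilcoxon needs exactly 2 groups")
    x <- split_vals[[1]]; y <- split_vals[[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 observations per group")
    if (length(unique(c(x, y))) == 1) {
      return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "wilcoxon (degenerate: all values identical)"))
    }
    exact <- wilcoxon_exact_mode(x, y)
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value),
         method = if (exact) "wilcoxon exact" else "wilcoxon normal approx.")
  } else {
    if (length(split_vals) < 2) stop("kruskal needs >= 2 groups")
    if (length(unique(values)) == 1) {
      return(list(statistic = 0, p_value = 1,
                  method = "kruskal-wallis (degenerate: all values identical)"))
    }
    ht <- stats::kruskal.test(values, factor(groups))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "kruskal-wallis")
  }
}

#' Compare per-cell marker expression between cell groups
#'
#' Wilcoxon rank-sum on transformed marker intensities, e.g. PD1 on CD8 T
#' cells adjacent to PanIN versus PDAC.
#'
#' @param cells Cell table (transformed intensities).
#' @param marker Marker column name.
#' @param groups Group label per cell (exactly two distinct labels).
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_marker_expression <- function(cells, marker, groups) {
  if (!marker %in% marker_columns(cells)) stop("unknown marker: ", marker)
  compare_groups(cells[[marker]], groups, test = "wilcoxon")
}
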