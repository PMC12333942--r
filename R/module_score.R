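#' Expression-bin-matched module score
#'
#' Per-spot mean expression of a gene signature minus the mean of pooled
#' control genes, where each signature gene contributes `n_ctrl` controls
#' sampled (with replacement when the bin is small) from its
#' mean-expression bin: genes are split by rank of mean expression across
#' spots into `n_bins` equal-size bins. Duplicated signature genes are
#' deduplicated; signature genes missing from the matrix are dropped with
#' a warning.
#'
#' @param D_norm Normalized gene x spot matrix (e.g. [normalize_cp10k()]),
#'   with rownames.
#' @param signature Character vector of signature genes.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls per signature gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return List with `score` (per spot), `signature_used`, `seed`.
#' @export
module_score <- function(D_norm, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  signature <- unique(signature)
  if (length(signature) == 0) stop("empty signature")
  present <- signature[signature %in% rownames(D_norm)]
  if (length(present) == 0) stop("no signature gene present in matrix")
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present),
            " signature gene(s) missing from matrix; dropped")
  }
  gene_mean <- rowMeans(D_norm)
  n_bins <- min(n_bins, nrow(D_norm))
  bin <- ceiling(rank(gene_mean, ties.method = "first") /
                   (nrow(D_norm) / n_bins))
  set.seed(seed)
  sig_idx <- match(present, rownames(D_norm))
  ctrl <- unlist(lapply(sig_idx, function(g) {
    pool <- setdiff(which(bin == bin[g]), sig_idx)
    if (length(pool) == 0) {
      # whole bin is signature; borrow the nearest non-signature bin
      pool <- setdiff(order(abs(gene_mean - gene_mean[g])), sig_idx)[1:10]
    }
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  sig_mean <- colMeans(D_norm[present, , drop = FALSE])
  ctrl_mean <- colMeans(D_norm[ctrl, , drop = FALSE])
  list(score = sig_mean - ctrl_mean, signature_used = present, seed = seed)
}

#' Correlate pattern weights with a module score
#'
#' Pearson correlation with its t-test p-value, and the R^2 of the simple
#' linear regression of score on weight (identical to r^2).
#'
#' @param weights Pattern weight per spot.
#' @param scores Module score per spot (same order).
#' @return List with `r`, `r_squared`, `p_value`, `n`.
#' @export
pattern_vs_module <- function(weights, scores) {
  if (length(weights) != length(scores)) stop("length mismatch")
  if (length(weights) < 3) stop("need n >= 3")
  if (stats::sd(weights) == 0 || stats::sd(scores) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(weights, scores, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(weights))
}

#' Compare pattern weights across TLS lesion classes
#'
#' Kruskal-Wallis across all classes plus unadjusted pairwise Wilcoxon
#' rank-sum tests (classes with fewer than 2 spots are excluded with a
#' warning).
#'
#' @param weights Pattern weight per spot.
#' @param classes Class label per spot.
#' @return List with `kruskal` (statistic, p_value) and `pairwise`
#'   data frame (group1, group2, statistic, p_value).
#' @export
compare_tls_classes <- function(weights, classes) {
  classes <- as.character(classes)
  tab <- table(classes)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding singleton class(es): ", paste(small, collapse = ", "))
    keep <- !classes %in% small
    weights <- weights[keep]; classes <- classes[keep]
  }
  if (length(unique(classes)) < 2) stop("need >= 2 classes with >= 2 spots")
  kw <- compare_groups(weights, classes, test = "kruskal")
  cls <- sort(unique(classes))
  pairs <- utils::combn(cls, 2)
  pw <- apply(pairs, 2, function(p) {
    sel <- classes %in% p
    res <- compare_groups(weights[sel], classes[sel], test = "wilcoxon")
    data.frame(group1 = p[1], group2 = p[2],
               statistic = res$statistic, p_value = res$p_value)
  })
  list(kruskal = kw, pairwise = do.call(rbind, pw))
}
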