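# Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1) for a
# set given its hit positions in a ranking. `w_ranked` is |stat| in rank
# order; `idx` the (unsorted) positions of the set genes.
gsea_es <- function(idx, w_ranked, n_total) {
  idx <- sort.int(idx)
  n <- length(idx)
  w <- w_ranked[idx]
  nr <- sum(w)
  n_miss <- n_total - n
  cum_hit <- if (nr > 0) cumsum(w) / nr else seq_len(n) / n
  k <- seq_len(n)
  dev_after <- cum_hit - (idx - k) / n_miss
  dev_before <- c(0, cum_hit[-n]) - (idx - k) / n_miss
  mx <- max(dev_after); mn <- min(dev_before)
  if (mx > -mn) mx else mn
}

#' Preranked gene set enrichment with permutation p-values
#'
#' Genes are ranked by a score (e.g. the pattern-marker robust z for one
#' pattern) and each gene set is tested with the weighted
#' Kolmogorov-Smirnov running-sum statistic (weight exponent 1). The null
#' is gene-label permutation: set membership is reassigned to random
#' positions in the ranking `n_perm` times, and the two-sided p-value is
#' `(1 + #{|ES_perm| >= |ES|}) / (n_perm + 1)`. NES normalizes ES by the
#' mean |ES| of same-signed permutations. P-values are BH-adjusted across
#' the sets tested together (i.e. within one pattern).
#'
#' @param scores Named numeric vector of gene scores (the universe).
#' @param gene_sets Named list of character vectors; members outside the
#'   universe are dropped (logged), sets with fewer than 3 represented
#'   genes are skipped (logged).
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer seed.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p_value`, `padj`.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(names(scores))) stop("scores must be named by gene")
  ord <- order(scores, decreasing = TRUE)
  ranked_genes <- names(scores)[ord]
  w_ranked <- abs(scores[ord])
  n_total <- length(scores)
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- unique(gene_sets[[nm]])
    inside <- members[members %in% ranked_genes]
    if (length(inside) < length(members)) {
      message("set '", nm, "': ", length(members) - length(inside),
              " gene(s) outside universe dropped")
    }
    if (length(inside) < 3) {
      message("set '", nm, "' has < 3 represented genes; skipped")
      return(NULL)
    }
    idx <- match(inside, ranked_genes)
    es <- gsea_es(idx, w_ranked, n_total)
    perm <- vapply(seq_len(n_perm), function(i) {
      gsea_es(sample.int(n_total, length(inside)), w_ranked, n_total)
    }, 0)
    p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
    same_sign <- perm[sign(perm) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    data.frame(set = nm, size = length(inside), es = es, nes = nes,
               p_value = p)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0),
                      padj = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
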