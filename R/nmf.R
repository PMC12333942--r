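#' Sparse non-negative matrix factorization by multiplicative updates
#'
#' Minimizes `0.5 * ||D - A P||_F^2 + alpha * (||A||_1 + ||P||_1)` over
#' non-negative `A` (gene x K amplitudes) and `P` (K x spot weights) with
#' the standard multiplicative update rules, which keep the objective
#' non-increasing. The best of `n_restarts` random initializations (by
#' final objective) is returned. `P` rows are rescaled to maximum 1, the
#' inverse scale absorbed into `A`, so pattern weights are comparable
#' across patterns.
#'
#' @param D Non-negative matrix (genes x spots), e.g. [log_transform()]
#'   output.
#' @param K Number of latent patterns, `1 <= K <= min(dim(D))`.
#' @param alpha L1 sparsity penalty on both factors (default 0.01).
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed (restart r uses `seed + r - 1`).
#' @param n_restarts Number of random initializations.
#' @return Object of class `pattern_decomposition`: list with `A`, `P`,
#'   `K`, `objective` (final), `objective_trace`, `seed`, `iterations`.
#' @export
fit_nmf <- function(D, K, alpha = 0.01, max_iter = 5000, tol = 1e-6,
                    seed = 1, n_restarts = 3) {
  D <- as.matrix(D)
  if (any(D < 0)) stop("D must be non-negative")
  if (K < 1 || K > min(dim(D))) stop("K must be in [1, min(dim(D))]")
  if (all(D == 0)) stop("D is all zero")
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    n_g <- nrow(D); n_s <- ncol(D)
    scale0 <- sqrt(mean(D) / K)
    A <- matrix(stats::runif(n_g * K, 0.1, 1) * scale0, n_g, K)
    P <- matrix(stats::runif(K * n_s, 0.1, 1) * scale0, K, n_s)
    obj <- function() {
      R <- D - A %*% P
      0.5 * sum(R * R) + alpha * (sum(A) + sum(P))
    }
    trace <- numeric(max_iter + 1)
    trace[1] <- obj()
    it <- 0
    for (i in seq_len(max_iter)) {
      it <- i
      A <- A * (D %*% t(P)) / (A %*% (P %*% t(P)) + alpha + eps)
      P <- P * (t(A) %*% D) / ((t(A) %*% A) %*% P + alpha + eps)
      trace[i + 1] <- obj()
      if (abs(trace[i] - trace[i + 1]) <= tol * max(trace[i], eps)) break
    }
    trace <- trace[1:(it + 1)]
    if (is.null(best) || trace[length(trace)] < best$objective) {
      best <- list(A = A, P = P, objective = trace[length(trace)],
                   objective_trace = trace, restart_seed = seed + r - 1,
                   iterations = it)
    }
  }
  A <- best$A; P <- best$P
  p_max <- apply(P, 1, max)
  p_max[p_max == 0] <- 1
  P <- P / p_max
  A <- sweep(A, 2, p_max, "*")
  rownames(A) <- rownames(D)
  pat <- paste0("pattern_", seq_len(K))
  colnames(A) <- pat; rownames(P) <- pat; colnames(P) <- colnames(D)
  structure(list(A = A, P = P, K = K,
                 objective = best$objective,
                 objective_trace = best$objective_trace,
                 seed = seed, iterations = best$iterations),
            class = "pattern_decomposition")
}

#' Fractional expression of genes across latent patterns
#'
#' The share of each gene's reconstructed expression attributable to each
#' pattern: with `r_k = sum_j P_kj`, the gene's total reconstructed
#' expression is `T_g = sum_k A_gk r_k` and its fractional expression
#' `f_gk = A_gk r_k / T_g`, which sums to 1 over patterns for every gene
#' with `T_g > 0`. Genes with `T_g = 0` get `NA` fractions and are flagged
#' for exclusion downstream.
#'
#' @param decomp A [fit_nmf()] result.
#' @return List with `f` (gene x pattern), `total` (`T_g`), and
#'   `expressed` (logical, `T_g > 0`).
#' @export
fractional_expression <- function(decomp) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  r <- rowSums(decomp$P)
  contrib <- sweep(decomp$A, 2, r, "*")
  total <- rowSums(contrib)
  f <- contrib / total
  f[total == 0, ] <- NA_real_
  list(f = f, total = total, expressed = total > 0)
}

# Quantile strata of total expression; strata with fewer than min_size
# genes are merged into their lower neighbour.
expression_strata <- function(total, n_strata, min_size = 5) {
  qs <- stats::quantile(total, probs = seq(0, 1, length.out = n_strata + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  stratum <- cut(total, breaks = unique(qs), labels = FALSE)
  repeat {
    tab <- table(stratum)
    small <- as.integer(names(tab))[tab < min_size]
    if (length(small) == 0 || length(tab) == 1) break
    s <- small[1]
    target <- if (s > min(stratum)) s - 1L else s + 1L
    message("merging expression stratum ", s, " (", tab[as.character(s)],
            " genes) into stratum ", target)
    stratum[stratum == s] <- target
    stratum <- as.integer(factor(stratum))
  }
  stratum
}

#' Pattern-marker statistic on fractional expression
#'
#' Genes are stratified into `n_strata` quantile bins (default tertiles:
#' low / medium / high) of total reconstructed expression `T_g`, so that a
#' gene's fractional expression is compared against genes of similar
#' overall expression. Within each (stratum, pattern) cell, a gene is
#' flagged as a marker of the pattern when its fractional expression
#' exceeds the Tukey upper fence `Q3 + fence * IQR`, and its robust score
#' is `z_gk = (f_gk - median) / (MAD + 1e-12)`. Flags and scores are
#' computed per pattern independently, so a gene can mark several patterns
#' (the statistic's defining multi-marker property).
#'
#' @param fe A [fractional_expression()] result.
#' @param n_strata Number of expression strata (default 3).
#' @param fence Tukey fence multiplier (default 1.5).
#' @return Data frame with one row per (expressed gene, pattern): `gene`,
#'   `pattern`, `f`, `stratum`, `z`, `marker`.
#' @export
pattern_marker_scores <- function(fe, n_strata = 3, fence = 1.5) {
  keep <- fe$expressed
  f <- fe$f[keep, , drop = FALSE]
  total <- fe$total[keep]
  genes <- rownames(f)
  if (is.null(genes)) genes <- paste0("gene_", which(keep))
  stratum <- expression_strata(total, n_strata)
  patterns <- colnames(f)
  out <- vector("list", length(patterns))
  for (k in seq_along(patterns)) {
    z <- numeric(nrow(f)); marker <- logical(nrow(f))
    for (s in unique(stratum)) {
      in_s <- stratum == s
      v <- f[in_s, k]
      q3 <- stats::quantile(v, 0.75, names = FALSE)
      iqr <- stats::IQR(v)
      med <- stats::median(v)
      mad <- stats::mad(v)
      marker[in_s] <- v > q3 + fence * iqr
      z[in_s] <- (v - med) / (mad + 1e-12)
    }
    out[[k]] <- data.frame(gene = genes, pattern = patterns[k],
                           f = f[, k], stratum = stratum,
                           z = z, marker = marker)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
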