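#' Plant non-negative latent patterns for the spot simulator
#'
#' Builds a gene x K amplitude matrix and a K x spot weight matrix in
#' which each pattern is active on a contiguous band of array columns
#' (smooth spatial support with soft edges). Every gene gets a lognormal
#' overall magnitude; `n_markers` genes per pattern are markers — about
#' 90% of their loading sits in their pattern — while background genes
#' spread their loading roughly evenly. Marker status is therefore
#' independent of overall expression, so markers occur in every
#' expression stratum, as in real transcriptomes.
#'
#' @param genes Gene names.
#' @param spots Spot positions data frame (`array_row`, `array_col`,
#'   `x_um`, `y_um`).
#' @param K Number of planted patterns.
#' @param n_markers Exclusive marker genes per pattern.
#' @param amp Median overall gene amplitude (log2-expression units).
#' @param amp_sdlog Log-sd of the per-gene amplitude.
#' @param tls_spots Optional indices of TLS spots; when given, pattern 1
#'   is supported on Gaussian bumps around the TLS discs (a TLS-coupled
#'   pattern) instead of a column band.
#' @param seed Integer seed.
#' @return List with `A_true`, `P_true`, and `markers` (list of marker
#'   gene names per pattern).
#' @export
plant_patterns <- function(genes, spots, K = 3, n_markers = 40,
                           amp = 2, amp_sdlog = 0.5, tls_spots = NULL,
                           seed = 1) {
  set.seed(seed)
  n_genes <- length(genes)
  if (K * n_markers > n_genes) stop("not enough genes for exclusive markers")
  magnitude <- stats::rlnorm(n_genes, log(amp), amp_sdlog)
  # background: roughly even share per pattern with some jitter
  share <- matrix(stats::runif(n_genes * K, 0.5, 1.5), n_genes, K)
  share <- share / rowSums(share)
  markers <- vector("list", K)
  pool <- sample(genes, K * n_markers)
  pool_idx <- match(pool, genes)
  for (k in seq_len(K)) {
    ix <- pool_idx[((k - 1) * n_markers + 1):(k * n_markers)]
    own <- stats::runif(n_markers, 0.85, 0.95)
    rest <- matrix(stats::runif(n_markers * (K - 1)), n_markers, K - 1)
    if (K > 1) {
      rest <- rest / rowSums(rest) * (1 - own)
      share[ix, -k] <- rest
    }
    share[ix, k] <- own
    markers[[k]] <- genes[ix]
  }
  A <- magnitude * share
  dimnames(A) <- list(genes, paste0("true_", seq_len(K)))
  # contiguous column bands with smooth falloff; pattern 1 optionally
  # TLS-coupled (bumps around the TLS discs)
  cols <- spots$array_col
  rng <- range(cols)
  centers <- seq(rng[1], rng[2], length.out = K + 2)[2:(K + 1)]
  width <- (rng[2] - rng[1]) / (K + 1)
  P <- t(vapply(seq_len(K), function(k) {
    exp(-((cols - centers[k])^2) / (2 * (width / 2)^2))
  }, numeric(nrow(spots))))
  if (!is.null(tls_spots)) {
    sigma <- 1.5 * stats::median(diff(sort(unique(spots$x_um))))
    bump <- rep(0, nrow(spots))
    for (i in tls_spots) {
      d2 <- (spots$x_um - spots$x_um[i])^2 + (spots$y_um - spots$y_um[i])^2
      bump <- pmax(bump, exp(-d2 / (2 * (2 * sigma)^2)))
    }
    P[1, ] <- bump
  }
  # baseline weight floor: every spot expresses every program a little,
  # so no spot is left without RNA
  P <- 0.15 + 0.85 * P
  dimnames(P) <- list(paste0("true_", seq_len(K)), NULL)
  list(A_true = A, P_true = P, markers = markers)
}

#' Configuration for the synthetic hex-lattice spot generator
#'
#' @param n_rows,n_cols Lattice extent; occupied spots have even
#'   (row + col).
#' @param spacing_um Centre-to-centre spot spacing (default 100 um).
#' @param n_genes Number of genes (ignored when `A_true` given).
#' @param K_true Number of planted patterns (ignored when `A_true` given).
#' @param A_true,P_true Optional explicit non-negative factors
#'   (gene x K and K x spot); defaults planted by [plant_patterns()].
#' @param signature_genes Genes elevated in TLS spots; default: 12 genes
#'   drawn from pattern 1's planted markers (a chemokine-like TLS
#'   signature).
#' @param delta Log2 elevation of signature genes in TLS spots (default 1).
#' @param tls_spots Integer indices of TLS spots; default: a disc of spots
#'   around the lattice position where pattern 1 peaks.
#' @param libsize_sdlog Log-sd of per-spot library-size factors
#'   `s_j ~ LogNormal(0, libsize_sdlog)`; default 0.1.
#' @param noise `"poisson"` (counts `~ Poisson(s_j (2^M - 1))`) or
#'   `"none"` (`round(2^M - 1)`).
#' @param dispersion Optional negative-binomial size parameter; when
#'   given, counts use `rnbinom(mu = s_j (2^M - 1), size = dispersion)`.
#' @param seed Integer seed.
#' @return A `visium_sim_config` list.
#' @export
visium_sim_config <- function(n_rows = 30, n_cols = 40, spacing_um = 100,
                              n_genes = 600, K_true = 3,
                              A_true = NULL, P_true = NULL,
                              signature_genes = NULL, delta = 1,
                              tls_spots = NULL, libsize_sdlog = 0.1,
                              noise = c("poisson", "none"),
                              dispersion = NULL, seed = 1) {
  noise <- match.arg(noise)
  if (is.null(A_true) != is.null(P_true))
    stop("supply both A_true and P_true or neither")
  if (!is.null(A_true)) {
    if (any(A_true < 0) || any(P_true < 0))
      stop("A_true and P_true must be non-negative")
    K_true <- ncol(A_true)
  }
  if (K_true < 1) stop("K_true must be >= 1")
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing_um = spacing_um,
                 n_genes = n_genes, K_true = K_true,
                 A_true = A_true, P_true = P_true,
                 signature_genes = signature_genes, delta = delta,
                 tls_spots = tls_spots, libsize_sdlog = libsize_sdlog,
                 noise = noise, dispersion = dispersion, seed = seed),
            class = "visium_sim_config")
}

#' Generate synthetic hex-lattice spot counts with planted patterns
#'
#' Mean log2 expression is `M = A_true P_true`; signature genes receive an
#' additional `delta` in TLS spots; counts are Poisson around
#' `s_j (2^M - 1)` (or deterministic rounding with `noise = "none"`).
#'
#' @param config A [visium_sim_config()].
#' @return List with `spots` (a [spot_matrix()]; TLS spots pre-labelled
#'   `TLS:1`) and `truth` (`A_true`, `P_true`, `markers`,
#'   `signature_genes`, `tls_spots`, `libsize`).
#' @export
generate_spot_data <- function(config) {
  stopifnot(inherits(config, "visium_sim_config"))
  set.seed(config$seed)
  lat <- hex_lattice(config$n_rows, config$n_cols, config$spacing_um)
  pos <- lat$spots
  n_spots <- nrow(pos)
  tls_spots <- config$tls_spots
  markers <- NULL
  if (is.null(config$A_true)) {
    if (is.null(tls_spots)) {
      # three TLS discs scattered along the lattice so the TLS + neighbour
      # subset spans the supports of every planted pattern
      ctr_cols <- stats::quantile(pos$array_col, c(0.2, 0.5, 0.8),
                                  names = FALSE)
      ctr_rows <- stats::quantile(pos$array_row, c(0.35, 0.65, 0.35),
                                  names = FALSE)
      tls_spots <- unique(unlist(lapply(1:3, function(i) {
        ctr <- which.min(abs(pos$array_col - ctr_cols[i]) * 2 +
                           abs(pos$array_row - ctr_rows[i]))
        d <- sqrt((pos$x_um - pos$x_um[ctr])^2 + (pos$y_um - pos$y_um[ctr])^2)
        which(d <= 2.2 * config$spacing_um)
      })))
    }
    genes <- sprintf("gene_%04d", seq_len(config$n_genes))
    planted <- plant_patterns(genes, pos, K = config$K_true,
                              n_markers = min(40, length(genes) %/%
                                                (2 * config$K_true)),
                              tls_spots = tls_spots, seed = config$seed)
    A <- planted$A_true; P <- planted$P_true; markers <- planted$markers
  } else {
    A <- config$A_true; P <- config$P_true
    genes <- rownames(A)
    if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(A)))
    rownames(A) <- genes
  }
  if (ncol(A) != nrow(P) || ncol(P) != n_spots)
    stop("factor dimensions do not match lattice")
  if (is.null(tls_spots)) {
    peak <- which.max(P[1, ])
    d <- sqrt((pos$x_um - pos$x_um[peak])^2 + (pos$y_um - pos$y_um[peak])^2)
    tls_spots <- which(d <= 2.2 * config$spacing_um)
  }
  sig <- config$signature_genes
  if (is.null(sig)) {
    sig <- if (!is.null(markers)) markers[[1]][seq_len(min(12, length(markers[[1]])))]
    else genes[seq_len(min(12, length(genes)))]
  }
  if (!all(sig %in% genes)) stop("signature genes outside gene universe")
  M <- A %*% P
  if (config$delta < 0 && abs(config$delta) > max(M))
    stop("negative delta larger than the signal")
  M[sig, tls_spots] <- M[sig, tls_spots] + config$delta
  mu <- 2^M - 1
  libsize <- stats::rlnorm(n_spots, 0, config$libsize_sdlog)
  if (config$noise == "none") {
    counts <- round(mu)
  } else if (!is.null(config$dispersion)) {
    counts <- matrix(stats::rnbinom(length(mu),
                                    mu = sweep(mu, 2, libsize, "*"),
                                    size = config$dispersion),
                     nrow(mu), ncol(mu))
  } else {
    counts <- matrix(stats::rpois(length(mu), sweep(mu, 2, libsize, "*")),
                     nrow(mu), ncol(mu))
  }
  barcodes <- sprintf("spot_%04d", seq_len(n_spots))
  dimnames(counts) <- list(genes, barcodes)
  positions <- data.frame(barcode = barcodes,
                          array_row = pos$array_row,
                          array_col = pos$array_col,
                          x_um = pos$x_um, y_um = pos$y_um)
  spots <- spot_matrix(counts, positions)
  spots$label[tls_spots] <- "TLS:1"
  list(spots = spots,
       truth = list(A_true = A, P_true = P, markers = markers,
                    signature_genes = sig, tls_spots = tls_spots,
                    libsize = libsize))
}

#' Write a synthetic spot dataset to disk
#'
#' MatrixMarket counts plus genes/barcodes TSV and positions CSV (10x-style
#' triplet layout), with ground truth as JSON.
#'
#' @param sim A [generate_spot_data()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_spot_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"),
             positions = file.path(dir, "positions.csv"),
             truth = file.path(dir, "truth.json"))
  Matrix::writeMM(sim$spots$counts, paths["mtx"])
  writeLines(sim$spots$genes, paths["genes"])
  writeLines(sim$spots$barcodes, paths["barcodes"])
  utils::write.csv(sim$spots$positions, paths["positions"], row.names = FALSE)
  truth <- sim$truth
  truth$A_true <- NULL; truth$P_true <- NULL  # large; regenerable from seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a spot dataset written by [write_spot_data()]
#'
#' @param dir Directory containing matrix.mtx, genes.tsv, barcodes.tsv,
#'   positions.csv.
#' @param composition Optional composition data frame to attach.
#' @return A [spot_matrix()].
#' @export
read_spot_data <- function(dir, composition = NULL) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes, barcodes)
  positions <- utils::read.csv(file.path(dir, "positions.csv"))
  spot_matrix(counts, positions, composition = composition)
}
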