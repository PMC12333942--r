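#' Configuration for the synthetic tissue cell-map generator
#'
#' Describes a stand-in tissue: axis-aligned rectangular regions with
#' lesion classes, per-class expected phenotype densities, planted TLS
#' discs, and a lognormal marker-intensity model. The defaults define the
#' study conditions used by the tests and the bundled demo.
#'
#' @param regions Data frame with columns `region_id`, `tissue_class`
#'   (normal/PanIN/PDAC/CP), `xmin`, `ymin`, `xmax`, `ymax` (um);
#'   rectangles must not overlap.
#' @param densities Data frame with columns `tissue_class`, `phenotype`,
#'   `per_mm2` (expected cells per mm^2); classes not listed get no
#'   background cells of that phenotype.
#' @param tls_specs Data frame (or NULL) with columns `center_x`,
#'   `center_y`, `radius_um`, `maturity` (`immature`/`mature`),
#'   `n_cells`; each disc must lie inside a region.
#' @param markers Character vector: the marker panel. Defaults to the
#'   union of markers in the packaged gate file.
#' @param mu_pos,mu_neg,sigma Lognormal intensity model: positive markers
#'   have median `mu_pos` (raw scale), negative `mu_neg`, both with log-sd
#'   `sigma`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `tissue_sim_config` list.
#' @export
tissue_sim_config <- function(regions = default_sim_regions(),
                              densities = default_sim_densities(),
                              tls_specs = default_sim_tls(),
                              markers = NULL,
                              mu_pos = 2.0, mu_neg = 0.2, sigma = 0.4,
                              seed = 1) {
  if (any(regions$xmax <= regions$xmin | regions$ymax <= regions$ymin))
    stop("all region areas must be > 0")
  if (any(densities$per_mm2 < 0)) stop("densities must be >= 0")
  if (!is.null(tls_specs) && nrow(tls_specs) > 0 &&
      any(tls_specs$radius_um <= 0)) stop("TLS radii must be > 0")
  n <- nrow(regions)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (regions$xmin[i] < regions$xmax[j] && regions$xmax[i] > regions$xmin[j] &&
          regions$ymin[i] < regions$ymax[j] && regions$ymax[i] > regions$ymin[j])
        stop("region rectangles overlap: ", regions$region_id[i], " and ",
             regions$region_id[j])
    }
  }
  if (is.null(markers)) {
    gates <- read_gates()
    markers <- sort(unique(unlist(lapply(gates, function(g)
      c(g$positive, g$negative)))))
  }
  structure(list(regions = regions, densities = densities,
                 tls_specs = tls_specs, markers = markers,
                 mu_pos = mu_pos, mu_neg = mu_neg, sigma = sigma,
                 seed = seed),
            class = "tissue_sim_config")
}

# 4 ROIs of 1 mm^2 per tissue class (multiple regions per class so
# per-class density comparisons have replicates), classes in columns.
default_sim_regions <- function() {
  classes <- c("normal", "PanIN", "PDAC", "CP")
  do.call(rbind, lapply(seq_along(classes), function(i) {
    data.frame(region_id = paste0("R_", classes[i], "_", 1:4),
               tissue_class = classes[i],
               xmin = (i - 1) * 2000, ymin = (0:3) * 1500,
               xmax = (i - 1) * 2000 + 1000, ymax = (0:3) * 1500 + 1000)
  }))
}

# Background immune/structural densities (cells per mm^2), loosely shaped
# like an immune-infiltrated pancreas: lesions carry more T cells, PDAC
# more Tregs, normal tissue mostly epithelial/unassigned.
default_sim_densities <- function() {
  tc <- c("normal", "PanIN", "PDAC", "CP")
  rbind(
    data.frame(tissue_class = tc, phenotype = "epithelial",
               per_mm2 = c(400, 300, 250, 150)),
    data.frame(tissue_class = tc, phenotype = "fibroblast",
               per_mm2 = c(100, 150, 250, 250)),
    data.frame(tissue_class = tc, phenotype = "macrophage",
               per_mm2 = c(30, 60, 100, 80)),
    data.frame(tissue_class = tc, phenotype = "dendritic_cell",
               per_mm2 = c(10, 20, 30, 25)),
    data.frame(tissue_class = tc, phenotype = "endothelial_HEV",
               per_mm2 = c(15, 20, 25, 25)),
    data.frame(tissue_class = tc, phenotype = "T_CD4",
               per_mm2 = c(20, 80, 120, 100)),
    data.frame(tissue_class = tc, phenotype = "T_CD8_cytotoxic",
               per_mm2 = c(15, 60, 50, 60)),
    data.frame(tissue_class = tc, phenotype = "Treg",
               per_mm2 = c(5, 10, 60, 25)),
    data.frame(tissue_class = tc, phenotype = "B_cell",
               per_mm2 = c(10, 25, 40, 35)),
    data.frame(tissue_class = tc, phenotype = "NK_cell",
               per_mm2 = c(5, 10, 15, 10)),
    data.frame(tissue_class = tc, phenotype = "T_CD4_exhausted",
               per_mm2 = c(0, 10, 40, 15)),
    data.frame(tissue_class = tc, phenotype = "T_CD4_central_memory",
               per_mm2 = c(5, 15, 25, 15)),
    data.frame(tissue_class = tc, phenotype = "T_CD8_memory",
               per_mm2 = c(5, 20, 40, 25)),
    data.frame(tissue_class = tc, phenotype = "B_proliferating",
               per_mm2 = c(0, 5, 15, 10)),
    data.frame(tissue_class = tc, phenotype = "T_CD4_senescent",
               per_mm2 = c(0, 5, 15, 10))
  )
}

# 20 planted TLS, half mature: immature in PanIN ROIs, mature in PDAC
# ROIs, both flavours in CP (as observed in inflamed pancreas). Two
# disc slots per 1 mm^2 ROI, well separated.
default_sim_tls <- function() {
  slots <- function(x0, y0s) {
    # y0s: ROI row indices to fill with 2 slots each
    do.call(rbind, lapply(y0s, function(j) {
      data.frame(center_x = x0 + c(300, 700),
                 center_y = j * 1500 + c(300, 700))
    }))
  }
  panin <- slots(2000, 0:3)[1:7, ]
  pdac <- slots(4000, 0:3)[1:7, ]
  cp <- slots(6000, 0:2)
  out <- rbind(panin, pdac, cp)
  out$radius_um <- 120
  out$maturity <- c(rep("immature", 7), rep("mature", 7),
                    c("mature", "immature")[rep(1:2, 3)])
  out$n_cells <- 250
  out
}

point_in_rect <- function(x, y, r) {
  x >= r$xmin & x <= r$xmax & y >= r$ymin & y <= r$ymax
}

# Marker intensity draws for n cells of one phenotype: positive markers
# lognormal around mu_pos, the rest around mu_neg.
draw_intensities <- function(n, phenotype, config, gate_lookup) {
  pos <- gate_lookup[[phenotype]]
  m <- matrix(stats::rlnorm(n * length(config$markers),
                            meanlog = log(config$mu_neg),
                            sdlog = config$sigma),
              nrow = n, dimnames = list(NULL, config$markers))
  for (mk in pos) {
    m[, mk] <- stats::rlnorm(n, meanlog = log(config$mu_pos),
                             sdlog = config$sigma)
  }
  m
}

#' Generate a synthetic segmented cell map with planted TLS
#'
#' Background cells are placed by a homogeneous Poisson point process per
#' (region, phenotype) at the configured density. TLS discs add lymphoid
#' aggregates: immature discs mix B and T cells uniformly (55% B, 45% T);
#' mature discs have an inner germinal-center core (radius 50% of the disc,
#' 40% of cells, CD20+CD21+CD23+ phenotype) surrounded by a T-cell annulus.
#' Marker intensities are lognormal draws with positive markers centred on
#' `mu_pos`.
#'
#' @param config A [tissue_sim_config()].
#' @return List with `cells` (cell table: cell_id, x_um, y_um, region_id,
#'   marker columns), `regions` (list of [region_polygon()]), and `truth`
#'   (per-cell true phenotype, per-TLS maturity/region, counts).
#' @export
generate_cell_map <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  set.seed(config$seed)
  gates <- read_gates()
  gate_lookup <- stats::setNames(lapply(gates, `[[`, "positive"),
                                 vapply(gates, `[[`, "", "name"))
  regions <- config$regions
  chunks <- list()
  # background Poisson field
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    area_mm2 <- (r$xmax - r$xmin) * (r$ymax - r$ymin) / 1e6
    dens <- config$densities[config$densities$tissue_class == r$tissue_class, ]
    for (j in seq_len(nrow(dens))) {
      n <- stats::rpois(1, dens$per_mm2[j] * area_mm2)
      if (n == 0) next
      chunks[[length(chunks) + 1]] <- data.frame(
        x_um = stats::runif(n, r$xmin, r$xmax),
        y_um = stats::runif(n, r$ymin, r$ymax),
        region_id = r$region_id,
        true_phenotype = dens$phenotype[j],
        tls_id = NA_integer_)
    }
  }
  # planted TLS discs
  tls_truth <- NULL
  if (!is.null(config$tls_specs) && nrow(config$tls_specs) > 0) {
    specs <- config$tls_specs
    tls_rows <- list()
    for (t in seq_len(nrow(specs))) {
      s <- specs[t, ]
      host <- which(point_in_rect(s$center_x, s$center_y, regions) &
                      point_in_rect(s$center_x - s$radius_um,
                                    s$center_y - s$radius_um, regions) &
                      point_in_rect(s$center_x + s$radius_um,
                                    s$center_y + s$radius_um, regions))
      if (length(host) == 0) stop("TLS disc ", t, " outside all regions")
      host <- host[1]
      # uniform positions in the disc via sqrt radius sampling
      n <- s$n_cells
      rad <- s$radius_um * sqrt(stats::runif(n))
      ang <- stats::runif(n, 0, 2 * pi)
      x <- s$center_x + rad * cos(ang)
      y <- s$center_y + rad * sin(ang)
      if (s$maturity == "mature") {
        inner <- rank(rad, ties.method = "first") <= round(0.4 * n)
        # germinal-center core: pull its cells into the inner half-disc
        shrink <- 0.5 * s$radius_um / max(rad[inner])
        x[inner] <- s$center_x + (x[inner] - s$center_x) * shrink
        y[inner] <- s$center_y + (y[inner] - s$center_y) * shrink
        # annulus: push T cells outside the core
        r_out <- rad[!inner]
        r_out <- 0.5 * s$radius_um +
          (r_out - min(r_out)) / (max(r_out) - min(r_out) + 1e-9) *
          0.5 * s$radius_um * 0.98
        x[!inner] <- s$center_x + r_out * cos(ang[!inner])
        y[!inner] <- s$center_y + r_out * sin(ang[!inner])
        pheno <- ifelse(inner, "B_germinal_center",
                        sample(c("T_CD4", "T_CD8_cytotoxic"), n, TRUE,
                               prob = c(0.6, 0.4)))
      } else {
        pheno <- sample(c("B_cell", "T_CD4", "T_CD8_cytotoxic"), n, TRUE,
                        prob = c(0.55, 0.27, 0.18))
      }
      chunks[[length(chunks) + 1]] <- data.frame(
        x_um = x, y_um = y,
        region_id = regions$region_id[host],
        true_phenotype = pheno,
        tls_id = t)
      tls_rows[[t]] <- data.frame(
        tls_id = t, maturity = s$maturity,
        region_id = regions$region_id[host],
        tissue_class = regions$tissue_class[host],
        center_x = s$center_x, center_y = s$center_y,
        radius_um = s$radius_um, n_cells = n)
    }
    tls_truth <- do.call(rbind, tls_rows)
  }
  placed <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(x_um = numeric(0), y_um = numeric(0),
               region_id = character(0), true_phenotype = character(0),
               tls_id = integer(0))
  n_cells <- nrow(placed)
  intens <- matrix(numeric(0), 0, length(config$markers),
                   dimnames = list(NULL, config$markers))
  if (n_cells > 0) {
    intens <- matrix(NA_real_, n_cells, length(config$markers),
                     dimnames = list(NULL, config$markers))
    for (ph in unique(placed$true_phenotype)) {
      ix <- which(placed$true_phenotype == ph)
      intens[ix, ] <- draw_intensities(length(ix), ph, config, gate_lookup)
    }
  }
  cells <- cbind(data.frame(cell_id = seq_len(n_cells),
                            x_um = placed$x_um, y_um = placed$y_um,
                            region_id = placed$region_id),
                 as.data.frame(intens))
  region_polys <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    region_rect(r$region_id, r$tissue_class, r$xmin, r$ymin, r$xmax, r$ymax)
  })
  list(cells = cells,
       regions = region_polys,
       truth = list(cells = data.frame(cell_id = cells$cell_id,
                                       phenotype = placed$true_phenotype,
                                       tls_id = placed$tls_id),
                    tls = tls_truth))
}

#' Write a synthetic cell map to disk
#'
#' Cell table as CSV, regions as GeoJSON, ground truth as JSON.
#'
#' @param sim A [generate_cell_map()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cell_map <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             regions = file.path(dir, "regions.geojson"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$cells, paths["cells"], row.names = FALSE)
  write_regions_geojson(sim$regions, paths["regions"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
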