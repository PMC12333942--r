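# Grid-bucketed DBSCAN on 2-D points. Core point: >= min_samples points
# (itself included) within eps. Border points join the first core cluster
# that reaches them; scan order is row order, so the result is deterministic
# for a given input order. Returns 0 for noise.
dbscan_points <- function(xy, eps, min_samples) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  gx <- floor(xy[, 1] / eps); gy <- floor(xy[, 2] / eps)
  bucket <- split(seq_len(n), paste(gx, gy, sep = "_"))
  neighbors_of <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(gx[i] + dx, gy[i] + dy, sep = "_")
      b <- bucket[[key]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps^2]
  }
  cluster <- integer(n)
  visited <- logical(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors_of(i)
    if (length(nb) < min_samples) next
    next_id <- next_id + 1L
    cluster[i] <- next_id
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (cluster[j] == 0L) cluster[j] <- next_id
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbors_of(j)
        if (length(nbj) >= min_samples) {
          queue <- c(queue, nbj[!visited[nbj] | cluster[nbj] == 0L])
        }
      }
    }
  }
  cluster
}

LYMPHOID_PHENOTYPES <- c("B_cell", "B_germinal_center", "B_proliferating",
                         "T_cell", "T_CD4", "T_CD8", "T_CD8_cytotoxic",
                         "T_CD8_memory", "T_CD4_exhausted",
                         "T_CD4_central_memory", "T_CD4_senescent", "Treg",
                         "NK_cell")

#' Detect candidate lymphoid aggregates
#'
#' Density-based clustering of lymphoid cells (B and T gates) as a
#' computational stand-in for pathologist annotation of TLS candidates.
#' Clusters with at least `min_cells` members become candidate records with
#' a convex-hull boundary.
#'
#' @param cells Phenotyped cell table.
#' @param eps_um Core-point radius in um; default 30 (2-3 lymphocyte
#'   diameters).
#' @param min_samples Minimum points within `eps_um` for a core point.
#' @param min_cells Minimum cluster size to report an aggregate.
#' @param lymphoid_phenotypes Phenotype labels counted as lymphoid.
#' @return List of `tls_record` objects (unassociated): `tls_id`,
#'   `cell_ids`, `hull` (vertex matrix, um), `hull_area_mm2`, `centroid`.
#' @export
detect_aggregates <- function(cells, eps_um = 30, min_samples = 10,
                              min_cells = 50,
                              lymphoid_phenotypes = LYMPHOID_PHENOTYPES) {
  if (eps_um <= 0) stop("eps_um must be > 0")
  lymph <- cells[cells$phenotype %in% lymphoid_phenotypes, , drop = FALSE]
  if (nrow(lymph) == 0) return(list())
  xy <- cbind(lymph$x_um, lymph$y_um)
  cl <- dbscan_points(xy, eps_um, min_samples)
  out <- list()
  tls_id <- 0L
  for (id in sort(unique(cl[cl > 0]))) {
    members <- which(cl == id)
    if (length(members) < min_cells) next
    tls_id <- tls_id + 1L
    hull_idx <- grDevices::chull(xy[members, , drop = FALSE])
    hull <- xy[members[hull_idx], , drop = FALSE]
    out[[tls_id]] <- structure(
      list(tls_id = tls_id,
           cell_ids = lymph$cell_id[members],
           hull = hull,
           hull_area_mm2 = shoelace_area(hull) / 1e6,
           centroid = colMeans(xy[members, , drop = FALSE]),
           lesion_class = NA_character_,
           lesion_distance_um = NA_real_),
      class = "tls_record")
  }
  out
}

#' Associate a TLS with its nearest lesion within a distance cutoff
#'
#' A TLS is assigned the class of the nearest lesion polygon whose boundary
#' lies within `max_dist_um` of the TLS hull boundary; aggregates farther
#' than the cutoff from every lesion are labelled `excluded` and dropped
#' from lesion-stratified analyses. Distance is the minimum between hull
#' and polygon boundaries (0 when they overlap). Ties within 1e-6 um are
#' broken by region order, with a message.
#'
#' @param tls A `tls_record`.
#' @param regions List of [region_polygon()] objects.
#' @param max_dist_um Association cutoff; default 250.
#' @param lesion_classes Region classes that qualify as lesions.
#' @return The record with `lesion_class` and `lesion_distance_um` filled.
#' @export
associate_tls <- function(tls, regions, max_dist_um = 250,
                          lesion_classes = c("PanIN", "PDAC", "CP")) {
  stopifnot(inherits(tls, "tls_record"))
  if (length(regions) == 0) stop("regions must be non-empty")
  lesions <- Filter(function(r) r$tissue_class %in% lesion_classes, regions)
  if (length(lesions) == 0) {
    tls$lesion_class <- "excluded"
    return(tls)
  }
  d <- vapply(lesions, function(r) {
    polygon_boundary_distance(tls$hull, r$vertices)
  }, 0)
  best <- which.min(d)
  ties <- which(abs(d - d[best]) < 1e-6)
  if (length(ties) > 1) {
    message("TLS ", tls$tls_id, " equidistant to regions ",
            paste(vapply(lesions[ties], `[[`, "", "region_id"),
                  collapse = ", "), "; keeping first by region order")
  }
  tls$lesion_distance_um <- d[best]
  tls$lesion_class <- if (d[best] <= max_dist_um) {
    lesions[[best]]$tissue_class
  } else {
    "excluded"
  }
  tls
}

#' Lymphoid composition of a TLS
#'
#' Fractions of each lymphoid phenotype among the aggregate's lymphoid
#' member cells (summing to 1); non-lymphoid members are counted
#' separately.
#'
#' @param tls A `tls_record`.
#' @param cells Phenotyped cell table containing the member cells.
#' @param lymphoid_phenotypes Labels counted as lymphoid.
#' @return List with `fractions` (named, sums to 1), `n_lymphoid`,
#'   `n_other`.
#' @export
tls_composition <- function(tls, cells,
                            lymphoid_phenotypes = LYMPHOID_PHENOTYPES) {
  members <- cells[cells$cell_id %in% tls$cell_ids, , drop = FALSE]
  lymph <- members$phenotype[members$phenotype %in% lymphoid_phenotypes]
  if (length(lymph) == 0) stop("TLS has no lymphoid member cells")
  tab <- table(lymph)
  fractions <- as.numeric(tab) / length(lymph)
  names(fractions) <- names(tab)
  list(fractions = fractions,
       n_lymphoid = length(lymph),
       n_other = nrow(members) - length(lymph))
}

#' Classify TLS maturity and report its maturity metrics
#'
#' A TLS is called mature when it contains at least `gc_min_cells`
#' germinal-center B cells (CD20+CD21+CD23+ gate) AND their centroid lies
#' in the hull interior (eroded by 10% of the hull radius) — a computable
#' proxy for a distinct germinal-center zone. Densities of
#' germinal-center B cells, dendritic cells (DCSIGN+), and high endothelial
#' venules (PDPN+) inside the hull are always reported, as is a B/T zone
#' segregation index (difference of mean centroid distance of T versus
#' GC-B members, normalized by hull radius; positive when B cells sit
#' deeper than T cells).
#'
#' @param tls A `tls_record`.
#' @param cells Phenotyped cell table (all cells, so non-member DCSIGN+ and
#'   PDPN+ cells inside the hull are counted for the density metrics).
#' @param gc_min_cells Minimum GC-B member count for maturity (default 10,
#'   strict `>=`).
#' @param gc_phenotype,dc_phenotype,hev_phenotype Gate labels used for the
#'   metrics.
#' @return List with `maturity` (`"mature"`/`"immature"`) and `metrics`
#'   (gc_b_count, gc_b_density, dc_density, hev_density per mm^2,
#'   gc_interior, zone_segregation).
#' @export
classify_maturity <- function(tls, cells, gc_min_cells = 10,
                              gc_phenotype = "B_germinal_center",
                              dc_phenotype = "dendritic_cell",
                              hev_phenotype = "endothelial_HEV") {
  hull_poly <- region_polygon(paste0("tls", tls$tls_id), "TLS", tls$hull)
  inside <- signed_boundary_distance(cbind(cells$x_um, cells$y_um),
                                     hull_poly) <= 0
  members <- cells$cell_id %in% tls$cell_ids
  gc_members <- which(members & cells$phenotype == gc_phenotype)
  hull_radius <- mean(sqrt((tls$hull[, 1] - tls$centroid[1])^2 +
                             (tls$hull[, 2] - tls$centroid[2])^2))
  gc_interior <- FALSE
  if (length(gc_members) > 0) {
    gc_centroid <- c(mean(cells$x_um[gc_members]), mean(cells$y_um[gc_members]))
    gc_interior <- signed_boundary_distance(gc_centroid, hull_poly) <=
      -0.1 * hull_radius
  }
  area <- tls$hull_area_mm2
  count_in <- function(pheno) sum(inside & cells$phenotype == pheno)
  t_members <- which(members & startsWith(cells$phenotype, "T"))
  zone_seg <- NA_real_
  if (length(t_members) > 0 && length(gc_members) > 0) {
    rad <- function(ix) mean(sqrt((cells$x_um[ix] - tls$centroid[1])^2 +
                                    (cells$y_um[ix] - tls$centroid[2])^2))
    zone_seg <- (rad(t_members) - rad(gc_members)) / hull_radius
  }
  mature <- length(gc_members) >= gc_min_cells && gc_interior
  list(maturity = if (mature) "mature" else "immature",
       metrics = list(gc_b_count = length(gc_members),
                      gc_b_density = count_in(gc_phenotype) / area,
                      dc_density = count_in(dc_phenotype) / area,
                      hev_density = count_in(hev_phenotype) / area,
                      gc_interior = gc_interior,
                      zone_segregation = zone_seg))
}

#' Flatten TLS records into a tidy table
#'
#' @param tls_list List of associated `tls_record`s.
#' @param cells Phenotyped cell table (for composition and maturity).
#' @param gc_min_cells Passed to [classify_maturity()].
#' @return Data frame, one row per TLS.
#' @export
tls_table <- function(tls_list, cells, gc_min_cells = 10) {
  rows <- lapply(tls_list, function(t) {
    m <- classify_maturity(t, cells, gc_min_cells = gc_min_cells)
    data.frame(tls_id = t$tls_id,
               n_cells = length(t$cell_ids),
               hull_area_mm2 = t$hull_area_mm2,
               lesion_class = t$lesion_class,
               lesion_distance_um = t$lesion_distance_um,
               maturity = m$maturity,
               gc_b_count = m$metrics$gc_b_count,
               gc_b_density = m$metrics$gc_b_density,
               dc_density = m$metrics$dc_density,
               hev_density = m$metrics$hev_density,
               zone_segregation = m$metrics$zone_segregation)
  })
  do.call(rbind, rows)
}
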