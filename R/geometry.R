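#' Construct a region polygon
#'
#' A region is a simple polygon in micron coordinates (image convention:
#' origin top-left, y increasing downward) carrying a lesion-class label.
#' Area is computed by the shoelace formula and reported in mm^2.
#'
#' @param region_id Character or integer identifier, unique within a region set.
#' @param tissue_class Lesion class label, one of `"normal"`, `"PanIN"`,
#'   `"PDAC"`, `"CP"` (other labels are allowed but ignored by lesion rules).
#' @param vertices Numeric matrix (n x 2) of polygon vertices in um, open ring
#'   (first vertex not repeated). At least 3 vertices.
#' @return An object of class `region_polygon`: a list with `region_id`,
#'   `tissue_class`, `vertices`, and `area_mm2`.
#' @export
region_polygon <- function(region_id, tissue_class, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) >= 2 &&
      all(vertices[1, ] == vertices[nrow(vertices), ])) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  }
  if (nrow(vertices) < 3) stop("polygon needs at least 3 distinct vertices")
  storage.mode(vertices) <- "double"
  area <- shoelace_area(vertices)
  if (area <= 0) stop("polygon area must be > 0")
  structure(
    list(region_id = as.character(region_id),
         tissue_class = as.character(tissue_class),
         vertices = vertices,
         area_mm2 = area / 1e6),
    class = "region_polygon"
  )
}

#' Rectangle helper for region polygons
#'
#' @param region_id,tissue_class Passed to [region_polygon()].
#' @param xmin,ymin,xmax,ymax Rectangle bounds in um.
#' @return A `region_polygon`.
#' @export
region_rect <- function(region_id, tissue_class, xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate rectangle")
  region_polygon(region_id, tissue_class,
                 rbind(c(xmin, ymin), c(xmax, ymin),
                       c(xmax, ymax), c(xmin, ymax)))
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Even-odd ray casting; points exactly on an edge may fall either side,
# callers that care about the boundary test distance == 0 first.
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  xj <- v[n, 1]; yj <- v[n, 2]
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

# Distance from each point to a single segment (a, b), vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Signed distance from points to a polygon boundary
#'
#' Negative inside the polygon, positive outside, zero on the boundary;
#' magnitude is the Euclidean distance to the nearest boundary segment.
#'
#' @param points Numeric matrix or data.frame with columns x, y (um), or a
#'   length-2 vector for a single point.
#' @param polygon A [region_polygon()].
#' @return Numeric vector of signed distances in um.
#' @export
signed_boundary_distance <- function(points, polygon) {
  stopifnot(inherits(polygon, "region_polygon"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  v <- polygon$vertices
  n <- nrow(v)
  px <- points[, 1]; py <- points[, 2]
  d <- rep(Inf, length(px))
  j <- c(2:n, 1)
  for (i in seq_len(n)) {
    d <- pmin(d, point_segment_distance(px, py, v[i, 1], v[i, 2],
                                        v[j[i], 1], v[j[i], 2]))
  }
  on_boundary <- d < 1e-9
  sgn <- ifelse(point_in_polygon(px, py, v), -1, 1)
  out <- sgn * d
  out[on_boundary] <- 0
  out
}

#' Classify cells relative to a polygon and a proximity band
#'
#' Implements the banded proximity rules used throughout the analysis
#' (e.g. a lesion plus a 200-250 um margin beyond its edge): `inside` when
#' the signed boundary distance is <= 0, `band` when it lies in
#' (0, band_um], `outside` beyond. The three labels partition the cells.
#'
#' @param cells Data frame with `x_um`, `y_um` columns.
#' @param polygon A [region_polygon()].
#' @param band_um Band width in um, >= 0.
#' @return Factor of labels `inside`/`band`/`outside`, one per cell.
#' @export
proximity_band <- function(cells, polygon, band_um) {
  if (band_um < 0) stop("band_um must be >= 0")
  d <- signed_boundary_distance(cbind(cells$x_um, cells$y_um), polygon)
  factor(ifelse(d <= 0, "inside", ifelse(d <= band_um, "band", "outside")),
         levels = c("inside", "band", "outside"))
}

#' Hexagonal spot lattice
#'
#' Visium-style array: occupied positions (row, col) satisfy (row + col)
#' even; two spots are adjacent iff their (|drow|, |dcol|) is (0,2) or (1,1),
#' giving interior spots exactly 6 neighbours. Centre-to-centre spacing
#' defaults to 100 um.
#'
#' @param n_rows,n_cols Lattice extent (rows 0..n_rows-1, cols 0..n_cols-1).
#' @param spacing_um Centre-to-centre distance between adjacent spots, um.
#' @return An object of class `hex_lattice` with a `spots` data.frame
#'   (`array_row`, `array_col`, `x_um`, `y_um`).
#' @export
hex_lattice <- function(n_rows, n_cols, spacing_um = 100) {
  if (spacing_um <= 0) stop("spacing must be > 0")
  grid <- expand.grid(array_col = 0:(n_cols - 1), array_row = 0:(n_rows - 1))
  grid <- grid[(grid$array_row + grid$array_col) %% 2 == 0, c(2, 1)]
  rownames(grid) <- NULL
  # (1,1) offset must have length spacing: dx = spacing/2, dy = spacing*sqrt(3)/2
  grid$x_um <- grid$array_col * spacing_um / 2
  grid$y_um <- grid$array_row * spacing_um * sqrt(3) / 2
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 spacing_um = spacing_um, spots = grid),
            class = "hex_lattice")
}

hex_key <- function(row, col) paste(row, col, sep = "_")

#' Breadth-first neighbour expansion on the hex lattice
#'
#' Returns all occupied spots within `depth` adjacency steps of any seed
#' spot, excluding the seeds themselves. This is the graph-distance reading
#' of "within 2 spots of a boundary": 2 lattice steps, not a metric radius.
#'
#' @param lattice A [hex_lattice()], or any data frame with `array_row`,
#'   `array_col` columns listing the occupied spots (e.g. the retained
#'   spots of a filtered array).
#' @param seed_spots Data frame (or matrix) with columns `array_row`,
#'   `array_col`; must all lie on the lattice.
#' @param depth Maximum number of adjacency steps, >= 1.
#' @return Data frame of neighbour spots (`array_row`, `array_col`).
#' @export
spot_neighbors <- function(lattice, seed_spots, depth) {
  spots <- if (inherits(lattice, "hex_lattice")) lattice$spots else
    as.data.frame(lattice)
  if (depth < 1) stop("depth must be >= 1")
  seed_spots <- as.data.frame(seed_spots)
  occupied <- hex_key(spots$array_row, spots$array_col)
  seeds <- hex_key(seed_spots$array_row, seed_spots$array_col)
  if (!all(seeds %in% occupied)) stop("seed spot not on lattice")
  offsets <- rbind(c(0, 2), c(0, -2), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  visited <- unique(seeds)
  frontier <- visited
  out <- character(0)
  for (step in seq_len(depth)) {
    fr <- do.call(rbind, strsplit(frontier, "_"))
    fr <- matrix(as.integer(fr), ncol = 2)
    cand <- unique(hex_key(rep(fr[, 1], each = 6) + rep(offsets[, 1], nrow(fr)),
                           rep(fr[, 2], each = 6) + rep(offsets[, 2], nrow(fr))))
    cand <- cand[cand %in% occupied & !(cand %in% visited)]
    if (length(cand) == 0) break
    visited <- c(visited, cand)
    out <- c(out, cand)
    frontier <- cand
  }
  if (length(out) == 0) {
    return(data.frame(array_row = integer(0), array_col = integer(0)))
  }
  m <- matrix(as.integer(do.call(rbind, strsplit(out, "_"))), ncol = 2)
  data.frame(array_row = m[, 1], array_col = m[, 2])
}

# Minimum distance between the boundaries of two polygons (vertex lists,
# open rings); 0 when they touch or overlap.
polygon_boundary_distance <- function(va, vb) {
  if (any(point_in_polygon(va[, 1], va[, 2], vb)) ||
      any(point_in_polygon(vb[, 1], vb[, 2], va))) {
    return(0)
  }
  na <- nrow(va); nb <- nrow(vb)
  ja <- c(2:na, 1); jb <- c(2:nb, 1)
  d <- Inf
  for (i in seq_len(nb)) {
    d <- min(d, min(point_segment_distance(va[, 1], va[, 2],
                                           vb[i, 1], vb[i, 2],
                                           vb[jb[i], 1], vb[jb[i], 2])))
  }
  for (i in seq_len(na)) {
    d <- min(d, min(point_segment_distance(vb[, 1], vb[, 2],
                                           va[i, 1], va[i, 2],
                                           va[ja[i], 1], va[ja[i], 2])))
  }
  d
}

#' Write a region set to GeoJSON
#'
#' Polygons are written as a FeatureCollection with properties `region_id`
#' and `class`.
#'
#' @param regions List of [region_polygon()] objects.
#' @param path Output file path.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- lapply(regions, function(p) {
    ring <- rbind(p$vertices, p$vertices[1, ])
    list(type = "Feature",
         properties = list(region_id = p$region_id, class = p$tissue_class),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region set from GeoJSON
#'
#' @param path GeoJSON file written by [write_regions_geojson()] or any
#'   FeatureCollection of Polygons with `region_id` and `class` properties.
#' @return List of `region_polygon` objects.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    region_polygon(f$properties$region_id, f$properties$class, v)
  })
}
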