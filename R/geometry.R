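# Cell geometry: polygon utilities and synthetic cell placement.
# Coordinate convention (fixed package-wide): 0-based, x = column, y = row,
# pixel (r, c) of the image matrix (1-based indices) has its center at
# (x = c - 1, y = r - 1). Polygon inclusion is by pixel center, even-odd rule.

# Vectorized even-odd (crossing number) point-in-polygon test.
# px, py: point coordinates; vx, vy: polygon vertices (open ring).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area (absolute).
polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simplicity check: no two non-adjacent edges properly intersect.
is_simple_polygon <- function(vx, vy) {
  n <- length(vx)
  if (n < 3L) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    if (abs(i - k) <= 1L || (i == 1L && k == n)) next
    if (segments_intersect(c(vx[edges[i, 1]], vy[edges[i, 1]]),
                           c(vx[edges[i, 2]], vy[edges[i, 2]]),
                           c(vx[edges[k, 1]], vy[edges[k, 1]]),
                           c(vx[edges[k, 2]], vy[edges[k, 2]]))) return(FALSE)
  }
  TRUE
}

#' Plan non-overlapping synthetic cell geometry
#'
#' Places one simple star-shaped polygon per neuron on a jittered grid, with
#' a nucleus disc and at least one neuromelanin blob strictly inside each
#' cell. Grid spacing guarantees pairwise-disjoint cells; each polygon
#' covers at least 100 interior pixels (minimum vertex radius 7 px with 12
#' vertices gives an inscribed disc of radius about 6.8 px).
#'
#' @param table a neuron table (one cell is planned per row), or an integer
#'   number of neurons.
#' @param image_shape `c(rows, cols)` of the target image.
#' @param seed integer seed for the jitter/radius draws.
#' @param n_vertices polygon vertex count.
#' @return object of class `imc_geometry`: list of cells (each with
#'   `neuron_id`, `case_id`, `polygon` (x,y matrix), `nucleus`, `melanin`)
#'   with the image shape as attribute. Zero neurons give an empty set.
#' @export
plan_geometry <- function(table, image_shape = c(512L, 512L), seed = 1L,
                          n_vertices = 12L) {
  if (is.numeric(table) && length(table) == 1L) {
    n <- as.integer(table)
    ids <- if (n > 0) sprintf("cell_%03d", seq_len(n)) else character()
    cases <- rep("case01", n)
  } else {
    n <- nrow(table); ids <- table$neuron_id; cases <- table$case_id
  }
  rows <- image_shape[1]; cols <- image_shape[2]
  geom <- structure(list(), class = "imc_geometry",
                    image_shape = as.integer(image_shape))
  if (n == 0L) return(geom)

  r_min <- 7
  per_row <- max(1L, floor(cols / 32)); per_col <- max(1L, floor(rows / 32))
  # shrink spacing if needed, but never below what r_min + gap requires
  while (per_row * per_col < n) {
    sx <- cols / (per_row + 1L); sy <- rows / (per_col + 1L)
    if (max(sx, sy) < 2 * r_min + 4)
      config_error(sprintf("cannot place %d non-overlapping cells in a %dx%d image",
                           n, rows, cols))
    if (sx >= sy) per_row <- per_row + 1L else per_col <- per_col + 1L
  }
  sx <- cols / per_row; sy <- rows / per_col
  if (min(sx, sy) < 2 * r_min + 4)
    config_error(sprintf("cannot place %d non-overlapping cells in a %dx%d image",
                         n, rows, cols))
  r_max <- min(12, (min(sx, sy) - 4) / 2)

  cells <- with_seed(substream_seed(seed, "geometry"), {
    slots <- utils::head(as.matrix(expand.grid(ix = seq_len(per_row) - 1L,
                                               iy = seq_len(per_col) - 1L)), n)
    lapply(seq_len(n), function(i) {
      cx0 <- (slots[i, "ix"] + 0.5) * sx; cy0 <- (slots[i, "iy"] + 0.5) * sy
      jit <- (min(sx, sy) / 2 - r_max - 2)
      cx <- cx0 + runif(1, -jit, jit); cy <- cy0 + runif(1, -jit, jit)
      ang <- sort(runif(n_vertices, 0, 2 * pi))
      rad <- runif(n_vertices, r_min, r_max)
      poly <- cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
      # nucleus and neuromelanin inside the inscribed disc of radius ~r_min
      na_ <- runif(1, 0, 2 * pi)
      nucleus <- list(cx = cx + 2.0 * cos(na_), cy = cy + 2.0 * sin(na_), r = 2.2)
      melanin <- list(list(cx = cx + 3.0 * cos(na_ + pi),
                           cy = cy + 3.0 * sin(na_ + pi), r = 1.6))
      list(neuron_id = ids[i], case_id = cases[i], polygon = poly,
           nucleus = nucleus, melanin = melanin)
    })
  })
  geom[seq_along(cells)] <- cells
  geom
}

#' Convert planned geometry to ROI polygons
#'
#' @param geometry an `imc_geometry` from [plan_geometry()].
#' @return list of ROI polygons (`neuron_id`, `case_id`, `vertices` matrix).
#' @export
roi_polygons <- function(geometry) {
  lapply(unclass(geometry), function(cell)
    list(neuron_id = cell$neuron_id, case_id = cell$case_id,
         vertices = cell$polygon))
}

#' Read/write neuron outline ROIs as GeoJSON
#'
#' A FeatureCollection of Polygons; feature properties carry `neuron_id` and
#' `case_id`. Coordinates are in the package's pixel convention (0-based,
#' x = column, y = row).
#'
#' @param rois list of ROI polygons as from [roi_polygons()].
#' @param path GeoJSON file path.
#' @return `read_rois()` returns a list of ROI polygons.
#' @export
write_rois <- function(rois, path) {
  features <- lapply(rois, function(r) {
    ring <- rbind(r$vertices, r$vertices[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(neuron_id = r$neuron_id, case_id = r$case_id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1L, as.list,
                                                         simplify = FALSE)))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    data_error("ROI file is not a GeoJSON FeatureCollection")
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) c(p[[1L]], p[[2L]])))
    if (nrow(ring) >= 2L &&
        all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    list(neuron_id = f$properties$neuron_id, case_id = f$properties$case_id,
         vertices = ring)
  })
}
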