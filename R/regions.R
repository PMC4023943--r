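# Sink-region partitions: ordered polygons in lon/lat space.
# Point-in-polygon is done directly in geographic coordinates (even-odd rule,
# boundary inclusive); adequate at shelf scale and for synthetic rectangles.

#' Construct a sink-region partition
#'
#' @param rings List of closed rings, each a numeric matrix with columns
#'   lon, lat; the first vertex need not be repeated (closure is enforced).
#' @param region_ids Integer ids; must be the consecutive sequence `1..I`.
#' @return An object of class `ss_regions`: a list with elements `region_ids`
#'   and `rings` (each ring closed, first vertex == last vertex).
#' @details Rings are checked for simplicity (no two non-adjacent edges may
#'   cross); overlap between distinct polygons is detected approximately (a
#'   vertex of one ring strictly inside another) and reported as a warning,
#'   not an error.
#' @export
region_partition <- function(rings, region_ids = seq_along(rings)) {
  region_ids <- as.integer(region_ids)
  if (anyDuplicated(region_ids)) stop("duplicate region_id")
  if (!identical(sort(region_ids), seq_along(rings)))
    stop("region_ids must be consecutive 1..I")
  ord <- order(region_ids)
  rings <- lapply(rings[ord], .close_ring)
  for (i in seq_along(rings)) {
    if (!.ring_is_simple(rings[[i]]))
      stop("polygon for region ", i, " is self-intersecting")
  }
  for (i in seq_along(rings)) {
    for (k in seq_along(rings)) {
      if (k == i) next
      v <- rings[[k]][-nrow(rings[[k]]), , drop = FALSE]
      if (any(.point_in_ring(v[, 1L], v[, 2L], rings[[i]], boundary = FALSE))) {
        warning(sprintf("regions %d and %d appear to overlap", i, k))
        break
      }
    }
  }
  structure(list(region_ids = seq_along(rings), rings = rings),
            class = "ss_regions")
}

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L) stop("ring must have two columns (lon, lat)")
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n < 3L) stop("ring must have at least 3 vertices")
  if (ring[1L, 1L] != ring[n, 1L] || ring[1L, 2L] != ring[n, 2L])
    ring <- rbind(ring, ring[1L, ])
  if (nrow(ring) < 4L) stop("closed ring must have at least 4 rows")
  dimnames(ring) <- list(NULL, c("lon", "lat"))
  ring
}

# segment-crossing check; rings here are small so O(n^2) is fine
.ring_is_simple <- function(ring) {
  n <- nrow(ring) - 1L
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (k in seq.int(i + 1L, n)) {
      adjacent <- (k == i + 1L) || (i == 1L && k == n)
      if (adjacent) next
      a <- seg(i); b <- seg(k)
      if (.segments_cross(a$p, a$q, b$p, b$q)) return(FALSE)
    }
  }
  TRUE
}

.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Number of regions in a partition
#' @param partition An `ss_regions` object.
#' @return Integer.
#' @export
n_regions <- function(partition) length(partition$region_ids)

#' @export
print.ss_regions <- function(x, ...) {
  cat(sprintf("Sink partition with %d regions\n", n_regions(x)))
  invisible(x)
}

# Vectorised even-odd point-in-ring test with boundary handling. Returns a
# logical vector over points. With boundary = TRUE points lying on an edge
# (within eps in the cross-product metric) count as inside.
.point_in_ring <- function(lon, lat, ring, boundary = TRUE, eps = 1e-12) {
  n <- nrow(ring) - 1L
  inside <- logical(length(lon))
  on_edge <- logical(length(lon))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
    x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    within <- lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    on_edge <- on_edge | (abs(cross) <= eps * (1 + abs(x2 - x1) + abs(y2 - y1)) & within)
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < x1 + (lat - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  if (boundary) inside | on_edge else inside & !on_edge
}

#' Read a sink-region partition from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each carrying an integer
#' `region_id` property.
#' @param path Path to a GeoJSON file.
#' @return An `ss_regions` partition.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  ids <- integer(0)
  rings <- list()
  for (feat in gj$features) {
    geom <- feat$geometry
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("non-polygon geometry in feature collection: ",
           if (is.null(geom$type)) "<missing>" else geom$type)
    rid <- feat$properties$region_id
    if (is.null(rid)) stop("feature is missing the region_id property")
    ring <- do.call(rbind, lapply(geom$coordinates[[1L]], function(pt)
      c(pt[[1L]], pt[[2L]])))
    ids <- c(ids, as.integer(rid))
    rings[[length(rings) + 1L]] <- ring
  }
  if (anyDuplicated(ids)) stop("duplicate region_id in ", path)
  region_partition(rings, ids)
}

#' Write a sink-region partition to GeoJSON
#' @param partition An `ss_regions` partition.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(partition, path) {
  stopifnot(inherits(partition, "ss_regions"))
  feats <- lapply(seq_along(partition$rings), function(i) {
    ring <- partition$rings[[i]]
    coords <- lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1L], ring[r, 2L]))
    list(type = "Feature",
         properties = list(region_id = partition$region_ids[i]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectangular-grid partition
#'
#' Builds a partition from a rows x cols grid of rectangles over a lon/lat
#' bounding box, optionally dropping cells; the 8-sink study layout is a 3x3
#' grid minus one cell.
#'
#' @param rows,cols Grid dimensions.
#' @param bounds Numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param exclude Integer vector of dropped cell indices, counted row-wise
#'   from the south-west corner.
#' @return An `ss_regions` partition with `rows*cols - length(exclude)`
#'   regions numbered consecutively.
#' @export
grid_partition <- function(rows, cols, bounds, exclude = integer(0)) {
  lon_b <- seq(bounds[1L], bounds[2L], length.out = cols + 1L)
  lat_b <- seq(bounds[3L], bounds[4L], length.out = rows + 1L)
  rings <- list()
  cell <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      cell <- cell + 1L
      if (cell %in% exclude) next
      rings[[length(rings) + 1L]] <- cbind(
        lon = c(lon_b[cc], lon_b[cc + 1L], lon_b[cc + 1L], lon_b[cc]),
        lat = c(lat_b[r], lat_b[r], lat_b[r + 1L], lat_b[r + 1L]))
    }
  }
  region_partition(rings)
}
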